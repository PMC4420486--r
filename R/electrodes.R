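#' Needle electrode specification
#'
#' Electrodes are parallel needles inserted along -z: an axis position in
#' the xy plane, an active (uninsulated, fixed-potential) tip spanning
#' `[tip_lo, tip_hi]` in z, and an insulated shaft from `tip_hi` up to the
#' domain top.
#'
#' @param x,y Axis position (world mm).
#' @param tip_lo,tip_hi Active-tip z range (world mm), `tip_lo < tip_hi`.
#' @param diameter Electrode diameter (mm), default 1.2.
#' @param id Integer electrode id.
#' @param role `"outer"` or `"center"`.
#' @return An object of class `electrode_spec`.
#' @export
electrode_spec <- function(x, y, tip_lo, tip_hi, diameter = 1.2, id = 1L,
                           role = "outer") {
  stopifnot(tip_hi > tip_lo, diameter > 0)
  structure(list(x = x, y = y, tip_lo = tip_lo, tip_hi = tip_hi,
                 diameter = diameter, id = as.integer(id), role = role),
            class = "electrode_spec")
}

#' Place electrodes around (or inside) the tumor
#'
#' Implements the standard layouts used per tumor size and treatment type:
#' \describe{
#'   \item{4 electrodes}{a square "box" around the tumor with every
#'     electrode `edge_offset` mm away from the tumor edge (axes at radial
#'     distance tumor radius + `edge_offset`, at 45, 135, 225, 315
#'     degrees).}
#'   \item{5 electrodes}{the same box plus one central electrode in the
#'     tumor.}
#'   \item{7 electrodes}{6 on a hexagon plus a central electrode. For ECT
#'     the hexagon surrounds the tumor with every electrode `edge_offset`
#'     mm from the tumor edge; for IRE of 30 mm tumors the hexagon sits
#'     inside the tumor at `hex_radius` mm (default 7) from the tumor
#'     center. One vertex lies on the +x axis.}
#' }
#' The tumor is positioned at the middle of the 40 mm active tip, except
#' for small (<= 10 mm) tumors with a large (>= 10 mm) perpendicular
#' vessel, where the insertion depth is reduced so the tip ends
#' `depth_override` mm past the tumor edge nearest the vessel, avoiding
#' electrodes running through the vessel.
#'
#' @param scene A [label_scene()]; tumor geometry is read from its `meta`
#'   (or measured from the tumor mask for patient-like scenes).
#' @param treatment `"ECT"` or `"IRE"`.
#' @param n_electrodes 4, 5 or 7.
#' @param edge_offset Box/hexagon offset from the tumor edge (mm).
#' @param hex_radius Center-to-electrode radius of the inside-tumor hexagon (mm).
#' @param diameter Electrode diameter (mm).
#' @param depth_override Tip overshoot past the near tumor edge (mm, 1 or 5)
#'   used when the shallow-insertion rule triggers.
#' @return List of [electrode_spec()] objects (class `electrode_set`).
#' @export
place_electrodes <- function(scene, treatment = c("ECT", "IRE"), n_electrodes,
                             edge_offset = 2, hex_radius = 7, diameter = 1.2,
                             depth_override = 1) {
  treatment <- match.arg(treatment)
  if (!n_electrodes %in% c(4L, 5L, 7L))
    stop("unknown electrode configuration: n_electrodes = ", n_electrodes)
  tl <- scene$meta$tip_length %||% 40

  tmask <- scene_mask(scene, "tumor")
  if (!any(tmask)) stop("scene has no tumor")
  axs <- scene_axes(scene)
  if (!is.null(scene$meta$tumor_center)) {
    ctr <- scene$meta$tumor_center
    cx <- ctr[1]; cy <- ctr[2]; cz <- ctr[3]
  } else {
    idx <- which(tmask, arr.ind = TRUE)
    cx <- mean(axs$x[idx[, 1]]); cy <- mean(axs$y[idx[, 2]])
    cz <- mean(axs$z[idx[, 3]])
  }
  # effective in-plane tumor radius (exact for the simplified sphere)
  rt <- if (!is.null(scene$meta$tumor_diameter)) {
    scene$meta$tumor_diameter / 2
  } else {
    idx <- which(tmask, arr.ind = TRUE)
    max(sqrt((axs$x[idx[, 1]] - cx)^2 + (axs$y[idx[, 2]] - cy)^2))
  }

  # shallow-insertion override for small tumors + large perpendicular vessel
  v <- scene$meta$vessel
  shallow <- !is.null(v) && identical(v$orientation, "perpendicular") &&
    v$diameter >= 10 && 2 * rt <= 10
  if (shallow) {
    tip_lo <- cz - (rt + depth_override)
    tip_hi <- tip_lo + tl
  } else {
    tip_lo <- cz - tl / 2
    tip_hi <- cz + tl / 2
  }

  xy <- switch(as.character(n_electrodes),
    "4" = ,
    "5" = {
      R <- rt + edge_offset                  # every needle 2 mm from the edge
      ang <- pi / 4 + (0:3) * pi / 2
      cbind(R * cos(ang), R * sin(ang))
    },
    "7" = {
      R <- if (treatment == "IRE" && 2 * rt > 20) hex_radius
           else rt + edge_offset
      ang <- (0:5) * pi / 3                  # one vertex on +x
      cbind(R * cos(ang), R * sin(ang))
    }
  )
  specs <- lapply(seq_len(nrow(xy)), function(i)
    electrode_spec(cx + xy[i, 1], cy + xy[i, 2], tip_lo, tip_hi,
                   diameter = diameter, id = i, role = "outer"))
  if (n_electrodes %in% c(5L, 7L))
    specs <- c(specs, list(electrode_spec(cx, cy, tip_lo, tip_hi,
                                          diameter = diameter,
                                          id = length(specs) + 1L,
                                          role = "center")))
  structure(specs, class = "electrode_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# xy voxel columns covered by an electrode (voxel-center membership, with a
# nearest-column fallback so thin electrodes on coarse grids stay rendered)
electrode_columns <- function(scene, e) {
  axs <- scene_axes(scene)
  re <- e$diameter / 2
  inx <- which(abs(axs$x - e$x) <= re)
  iny <- which(abs(axs$y - e$y) <= re)
  cols <- NULL
  if (length(inx) && length(iny)) {
    g <- expand.grid(i = inx, j = iny)
    keep <- (axs$x[g$i] - e$x)^2 + (axs$y[g$j] - e$y)^2 <= re^2
    if (any(keep)) cols <- as.matrix(g[keep, , drop = FALSE])
  }
  if (is.null(cols) || nrow(cols) == 0) {
    cols <- cbind(i = which.min(abs(axs$x - e$x)),
                  j = which.min(abs(axs$y - e$y)))
  }
  cols
}

#' Rasterize electrodes into a scene
#'
#' Voxels whose centers fall inside an electrode along its active tip
#' become `electrode_active`; the shaft above the tip up to the domain top
#' becomes `electrode_insulated` (a no-current region). Rasterization is
#' idempotent.
#'
#' @param scene A [label_scene()].
#' @param electrodes List of [electrode_spec()] (an `electrode_set`).
#' @return A new [label_scene()] with electrode labels and
#'   `meta$electrodes` set.
#' @export
rasterize_electrodes <- function(scene, electrodes) {
  if (length(electrodes) == 0) return(scene)
  axs <- scene_axes(scene)
  lab <- scene$labels
  for (e in electrodes) {
    if (e$x < min(axs$x) || e$x > max(axs$x) ||
        e$y < min(axs$y) || e$y > max(axs$y) ||
        e$tip_lo < min(axs$z) - scene$spacing[3] / 2)
      stop("electrode ", e$id, " outside the domain")
    cols <- electrode_columns(scene, e)
    kz_tip <- which(axs$z >= e$tip_lo & axs$z <= e$tip_hi)
    kz_shaft <- which(axs$z > e$tip_hi)
    if (length(kz_tip) == 0) stop("electrode ", e$id, " active tip outside the domain")
    for (r in seq_len(nrow(cols))) {
      lab[cols[r, 1], cols[r, 2], kz_tip] <- LABELS[["electrode_active"]]
      if (length(kz_shaft))
        lab[cols[r, 1], cols[r, 2], kz_shaft] <- LABELS[["electrode_insulated"]]
    }
  }
  out <- scene
  out$labels <- lab
  out$meta$electrodes <- electrodes
  out
}

#' Adjust electrode positions that would puncture a vessel
#'
#' For each electrode whose active tip would intersect vessel voxels (wall
#' or blood), searches lateral offsets on a polar grid (radii in `step` mm
#' increments up to `max_offset`, 8 directions) and applies the smallest
#' offset that clears the vessel while staying inside the domain. If no
#' such offset exists the electrode keeps its position and is flagged as a
#' breach -- punctures are sometimes unavoidable when the vessel is larger
#' than the tumor.
#'
#' @param scene A [label_scene()] containing the vessel.
#' @param electrodes An `electrode_set`.
#' @param step Offset search step (mm).
#' @param max_offset Largest lateral offset tried (mm).
#' @return List with `electrodes` (possibly moved) and `report`
#'   (data.frame: id, collided, moved, offset_mm, breach).
#' @export
resolve_electrode_vessel_collisions <- function(scene, electrodes,
                                                step = 0.5, max_offset = 5) {
  vmask <- scene_mask(scene, c("vessel_wall", "blood"))
  axs <- scene_axes(scene)
  xr <- range(axs$x); yr <- range(axs$y)

  hits_vessel <- function(e) {
    kz <- which(axs$z >= e$tip_lo & axs$z <= e$tip_hi)
    if (length(kz) == 0) return(FALSE)
    cols <- electrode_columns(scene, e)
    for (r in seq_len(nrow(cols)))
      if (any(vmask[cols[r, 1], cols[r, 2], kz])) return(TRUE)
    FALSE
  }

  out <- electrodes
  rep <- data.frame(id = integer(), collided = logical(), moved = logical(),
                    offset_mm = numeric(), breach = logical())
  for (i in seq_along(electrodes)) {
    e <- electrodes[[i]]
    coll <- hits_vessel(e)
    moved <- FALSE; off <- 0; breach <- FALSE
    if (coll) {
      found <- FALSE
      for (r in seq(step, max_offset, by = step)) {
        for (ang in (0:7) * pi / 4) {
          cand <- e
          cand$x <- e$x + r * cos(ang)
          cand$y <- e$y + r * sin(ang)
          if (cand$x < xr[1] || cand$x > xr[2] ||
              cand$y < yr[1] || cand$y > yr[2]) next
          if (!hits_vessel(cand)) {
            out[[i]] <- cand; moved <- TRUE; off <- r; found <- TRUE
            break
          }
        }
        if (found) break
      }
      breach <- !found
    }
    rep <- rbind(rep, data.frame(id = e$id, collided = coll, moved = moved,
                                 offset_mm = off, breach = breach))
  }
  class(out) <- "electrode_set"
  list(electrodes = out, report = rep)
}
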