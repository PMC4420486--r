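#' Build a simplified sphere-tumor / cylinder-vessel scene
#'
#' Constructs the parametric voxel model used in the simplified study: a
#' spherical tumor centered in a block of liver, optionally accompanied by
#' a cylindrical hepatic vessel (two-layer: wall plus blood, the wall being
#' 10% of the vessel outer diameter) at a given surface-to-surface distance
#' from the tumor. The vessel is oriented either perpendicular to the
#' electrode axes (cylinder axis along x, displaced below the tumor along
#' z) or parallel to them (axis along z, displaced along x). The domain is
#' sized to accommodate the needle electrodes (1.2 mm diameter, 40 mm
#' active tip, tumor at the tip midpoint) plus `padding` mm of liver.
#'
#' @param tumor_diameter Tumor (sphere) diameter in mm.
#' @param vessel_diameter Vessel outer diameter in mm, or `NULL` for a
#'   vessel-free scene.
#' @param distance Surface-to-surface tumor-vessel distance in mm (>= 0).
#' @param orientation `"perpendicular"` or `"parallel"` (to the electrodes).
#' @param spacing Isotropic voxel spacing in mm.
#' @param padding Liver margin (mm) beyond the outermost structure.
#' @param tip_length Electrode active-tip length in mm.
#' @param edge_offset Electrode box/hexagon offset from the tumor edge (mm).
#' @return A [label_scene()] with `meta` describing the construction.
#' @examples
#' sc <- build_simplified_scene(10, vessel_diameter = 5, distance = 1,
#'                              orientation = "parallel", spacing = 1)
#' @export
build_simplified_scene <- function(tumor_diameter,
                                   vessel_diameter = NULL,
                                   distance = 0,
                                   orientation = c("perpendicular", "parallel"),
                                   spacing = 0.5,
                                   padding = 10,
                                   tip_length = 40,
                                   edge_offset = 2) {
  orientation <- match.arg(orientation)
  stopifnot(tumor_diameter > 0, spacing > 0, padding >= 0)
  rt <- tumor_diameter / 2
  has_vessel <- !is.null(vessel_diameter)
  if (has_vessel) {
    stopifnot(vessel_diameter > 0)
    if (distance < 0)
      stop("vessel overlaps the tumor interior (distance must be >= 0)")
  }
  rv <- if (has_vessel) vessel_diameter / 2 else 0

  # electrode allowance: box/hexagon radius plus the electrode diameter
  elec_allow <- rt + edge_offset + 1.2

  half_x <- elec_allow
  half_y <- elec_allow
  z_lo <- -tip_length / 2
  z_hi <- tip_length / 2
  if (has_vessel) {
    if (orientation == "parallel") {
      xc <- rt + distance + rv          # vessel axis at (xc, 0), along z
      half_x <- max(half_x, xc + rv)
      half_y <- max(half_y, rv)
    } else {
      zc <- -(rt + distance + rv)       # vessel axis at (y=0, zc), along x
      half_y <- max(half_y, rv)
      z_lo <- min(z_lo, zc - rv)
      # shallow-insertion override for small tumors with large perpendicular
      # vessels: tip ends depth_override past the near tumor edge, so the
      # tip top rises to tip_length - rt - 1 at the default 1 mm override
      if (vessel_diameter >= 10 && tumor_diameter <= 10)
        z_hi <- max(z_hi, tip_length - rt - 1)
    }
  }
  half_x <- half_x + padding
  half_y <- half_y + padding
  z_lo <- z_lo - padding
  z_hi <- z_hi + padding

  ax <- sym_axis(half_x, spacing)
  ay <- sym_axis(half_y, spacing)
  az <- seq(-spacing * ceiling(-z_lo / spacing), spacing * ceiling(z_hi / spacing),
            by = spacing)

  nx <- length(ax); ny <- length(ay); nz <- length(az)
  lab <- array(LABELS[["liver"]], dim = c(nx, ny, nz))

  # tumor sphere
  d2 <- outer(outer(ax^2, ay^2, "+"), az^2, "+")
  lab[d2 <= rt^2] <- LABELS[["tumor"]]

  vmeta <- NULL
  if (has_vessel) {
    tw <- 0.1 * vessel_diameter
    if (tw < spacing) {
      warning("vessel wall (", tw, " mm) thinner than one voxel; rendered at ",
              spacing, " mm")
      tw <- spacing
    }
    rb <- max(rv - tw, 0)
    if (orientation == "parallel") {
      r2 <- outer((ax - xc)^2, ay^2, "+")                 # in xy, along z
      wall <- r2 <= rv^2 & r2 > rb^2
      core <- r2 <= rb^2
      for (k in seq_len(nz)) {
        sl <- lab[, , k]
        sl[wall] <- LABELS[["vessel_wall"]]
        sl[core] <- LABELS[["blood"]]
        lab[, , k] <- sl
      }
      vmeta <- list(axis = "z", center = c(xc, 0))
    } else {
      r2 <- outer(ay^2, (az - zc)^2, "+")                 # in yz, along x
      wall <- r2 <= rv^2 & r2 > rb^2
      core <- r2 <= rb^2
      for (i in seq_len(nx)) {
        sl <- lab[i, , ]
        sl[wall] <- LABELS[["vessel_wall"]]
        sl[core] <- LABELS[["blood"]]
        lab[i, , ] <- sl
      }
      vmeta <- list(axis = "x", center = c(0, zc))
    }
    vmeta <- c(vmeta, list(diameter = vessel_diameter, distance = distance,
                           orientation = orientation, wall_thickness = tw))
  }

  label_scene(
    lab, spacing = spacing,
    origin = c(ax[1], ay[1], az[1]),
    meta = list(kind = "simplified", tumor_diameter = tumor_diameter,
                tumor_center = c(0, 0, 0), vessel = vmeta,
                tip_length = tip_length, edge_offset = edge_offset,
                padding = padding)
  )
}

# symmetric voxel-center axis covering [-half, half], a center voxel at 0
sym_axis <- function(half, spacing) {
  n <- ceiling(half / spacing)
  seq(-n, n) * spacing
}

#' Build a synthetic patient-like scene
#'
#' Generates a stand-in for a segmented real-patient liver model: an
#' ellipsoidal tumor abutting a large vessel (default 15 mm diameter,
#' emulating proximity to the vena cava or a main hepatic vein branch)
#' running head-to-foot, with optional smaller branch vessels. The scene is
#' synthetic: it emulates the geometric situation of tumors in the close
#' vicinity of major hepatic vessels, not any particular patient anatomy.
#' Deterministic for a fixed `seed` (branch placement uses its own RNG
#' stream and does not disturb the global RNG state).
#'
#' @param seed Integer seed controlling branch placement.
#' @param tumor_extents Tumor bounding-box extents (mm), length 3
#'   (default emulates a 15 x 11 mm tumor).
#' @param vessel_diameter Main vessel outer diameter (mm).
#' @param gap Tumor-vessel surface gap (mm), default 1.
#' @param n_branches Number of branch vessels (0-2).
#' @param spacing Voxel spacing (mm).
#' @param padding Liver margin (mm).
#' @param tip_length Electrode active-tip length (mm).
#' @return A [label_scene()].
#' @export
build_patient_like_scene <- function(seed,
                                     tumor_extents = c(15, 11, 11),
                                     vessel_diameter = 15,
                                     gap = 1,
                                     n_branches = 1,
                                     spacing = 1,
                                     padding = 8,
                                     tip_length = 40) {
  stopifnot(length(tumor_extents) == 3, all(tumor_extents > 0),
            vessel_diameter > 0, n_branches >= 0)
  semi <- tumor_extents / 2
  rv <- vessel_diameter / 2
  xc <- semi[1] + gap + rv

  elec_allow <- max(semi[1:2]) + 2 + 1.2
  half_x <- max(elec_allow, xc + rv) + padding
  half_y <- max(elec_allow, rv, semi[2]) + padding
  half_z <- max(tip_length / 2, semi[3]) + padding

  ax <- sym_axis(half_x, spacing)
  ay <- sym_axis(half_y, spacing)
  az <- sym_axis(half_z, spacing)
  nx <- length(ax); ny <- length(ay); nz <- length(az)
  lab <- array(LABELS[["liver"]], dim = c(nx, ny, nz))

  # ellipsoidal tumor at the origin
  e2 <- outer(outer((ax / semi[1])^2, (ay / semi[2])^2, "+"), (az / semi[3])^2, "+")
  lab[e2 <= 1] <- LABELS[["tumor"]]

  paint_cyl_z <- function(lab, cx, cy, r_out, tw) {
    rb <- max(r_out - tw, 0)
    r2 <- outer((ax - cx)^2, (ay - cy)^2, "+")
    wall <- r2 <= r_out^2 & r2 > rb^2
    core <- r2 <= rb^2
    for (k in seq_len(nz)) {
      sl <- lab[, , k]
      sl[wall & sl != LABELS[["tumor"]]] <- LABELS[["vessel_wall"]]
      sl[core & sl != LABELS[["tumor"]]] <- LABELS[["blood"]]
      lab[, , k] <- sl
    }
    lab
  }

  tw_main <- max(0.1 * vessel_diameter, spacing)
  lab <- paint_cyl_z(lab, xc, 0, rv, tw_main)

  # branches drawn from a private RNG stream
  if (n_branches > 0) {
    rng <- local({
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(as.integer(seed))
      on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
      })
      list(z = runif(n_branches, -half_z * 0.5, half_z * 0.5),
           dir = sample(c(-1, 1), n_branches, replace = TRUE))
    })
    bd <- 0.4 * vessel_diameter                 # branch diameter
    tw_b <- max(0.1 * bd, spacing)
    rb_out <- bd / 2
    rb_in <- max(rb_out - tw_b, 0)
    for (b in seq_len(n_branches)) {
      zb <- rng$z[b]
      # branch along y at (x = xc, z = zb), one side of the main vessel
      r2 <- outer((ax - xc)^2, (az - zb)^2, "+")
      wall <- r2 <= rb_out^2 & r2 > rb_in^2
      core <- r2 <= rb_in^2
      ysel <- if (rng$dir[b] > 0) which(ay >= 0) else which(ay <= 0)
      for (j in ysel) {
        sl <- lab[, j, ]
        sl[wall & sl == LABELS[["liver"]]] <- LABELS[["vessel_wall"]]
        sl[core & sl == LABELS[["liver"]]] <- LABELS[["blood"]]
        lab[, j, ] <- sl
      }
    }
  }

  label_scene(
    lab, spacing = spacing, origin = c(ax[1], ay[1], az[1]),
    meta = list(kind = "patient_like", seed = seed,
                tumor_extents = tumor_extents, tumor_center = c(0, 0, 0),
                vessel = list(axis = "z", center = c(xc, 0),
                              diameter = vessel_diameter, gap = gap,
                              wall_thickness = tw_main),
                tip_length = tip_length, edge_offset = 2, padding = padding)
  )
}
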