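# In-plane (xy) binary morphology on 3-D logical arrays. Dilation/erosion
# use a discrete disk structuring element of the given voxel radius; these
# are deliberately tiny shift-and-combine implementations (radii here are a
# few voxels at most).

disk_offsets <- function(r) {
  r <- as.integer(r)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= r^2 + 1e-9, , drop = FALSE]
}

shift_mask <- function(mask, dx = 0L, dy = 0L) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  sx <- xs - dx; sy <- ys - dy
  okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]
  out[xs[okx], ys[oky], ] <- mask[sx[okx], sy[oky], , drop = FALSE]
  out
}

dilate_xy <- function(mask, r) {
  if (r <= 0) return(mask)
  off <- disk_offsets(r)
  out <- array(FALSE, dim = dim(mask))
  for (k in seq_len(nrow(off)))
    out <- out | shift_mask(mask, off$dx[k], off$dy[k])
  out
}

erode_xy <- function(mask, r) {
  if (r <= 0) return(mask)
  off <- disk_offsets(r)
  out <- array(TRUE, dim = dim(mask))
  for (k in seq_len(nrow(off)))
    out <- out & shift_mask(mask, off$dx[k], off$dy[k])
  out
}

#' Segmentation-error perturbation specification
#'
#' Describes one of the six transformations used to emulate errors of
#' automatic vessel segmentation: uniform enlarging or shrinking of the
#' vessel mask, or an in-plane shift in one of four directions. Magnitudes
#' are in image pixels; the study uses 1 px (the segmentation algorithm's
#' average error, rounded from 0.9) and 3 px (its maximum error, rounded
#' from 2.8). `px_mm` converts pixels to mm (MRI in-plane pixel size).
#'
#' @param kind One of `"enlarge"`, `"shrink"`, `"shift_left"`,
#'   `"shift_right"`, `"shift_up"`, `"shift_down"`.
#' @param magnitude Non-negative integer, in pixels.
#' @param px_mm Pixel size in mm (default 1).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(kind = c("enlarge", "shrink", "shift_left",
                                       "shift_right", "shift_up", "shift_down"),
                              magnitude, px_mm = 1) {
  kind <- match.arg(kind)
  stopifnot(magnitude >= 0, magnitude == round(magnitude), px_mm > 0)
  structure(list(kind = kind, magnitude = as.integer(magnitude), px_mm = px_mm),
            class = "perturbation_spec")
}

#' Apply a segmentation-error perturbation to the vessel mask
#'
#' Enlarge/shrink apply in-plane (xy) morphological dilation/erosion of the
#' full vessel mask (wall + blood) by the perturbation magnitude; shifts
#' translate the mask along the named in-plane axis (left/right = -x/+x,
#' up/down = +y/-y). Voxels vacated by the vessel revert to liver; voxels
#' newly claimed by the vessel lose their previous tissue label. The wall
#' is re-derived as 10% of the perturbed outer diameter (at least one
#' voxel). All other labels are untouched.
#'
#' @param scene A [label_scene()] containing a vessel.
#' @param spec A [perturbation_spec()].
#' @return A perturbed [label_scene()].
#' @export
perturb_vessel <- function(scene, spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  vmask <- scene_mask(scene, c("vessel_wall", "blood"))
  if (!any(vmask)) stop("scene contains no vessel")
  if (spec$magnitude == 0) return(scene)

  r_vox <- max(1L, as.integer(round(spec$magnitude * spec$px_mm / scene$spacing[1])))
  new_mask <- switch(spec$kind,
    enlarge     = dilate_xy(vmask, r_vox),
    shrink      = erode_xy(vmask, r_vox),
    shift_left  = shift_mask(vmask, dx = -r_vox),
    shift_right = shift_mask(vmask, dx = +r_vox),
    shift_up    = shift_mask(vmask, dy = +r_vox),
    shift_down  = shift_mask(vmask, dy = -r_vox)
  )
  if (!any(new_mask))
    stop("perturbation '", spec$kind, "' by ", spec$magnitude,
         " px eliminates the vessel entirely (degenerate geometry)")

  # wall thickness from the perturbed outer diameter (area-equivalent,
  # averaged over slices containing vessel)
  per_slice <- apply(new_mask, 3, sum)
  area_mm2 <- mean(per_slice[per_slice > 0]) * scene$spacing[1] * scene$spacing[2]
  d_outer <- 2 * sqrt(area_mm2 / pi)
  tw <- max(0.1 * d_outer, max(scene$spacing[1:2]))
  t_vox <- max(1L, as.integer(round(tw / scene$spacing[1])))
  blood <- erode_xy(new_mask, t_vox)
  wall <- new_mask & !blood

  lab <- scene$labels
  lab[vmask & !new_mask] <- LABELS[["liver"]]
  lab[wall] <- LABELS[["vessel_wall"]]
  lab[blood] <- LABELS[["blood"]]

  out <- scene
  out$labels <- lab
  out$meta$perturbation <- spec
  out
}
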