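# Label codes used in every voxelized scene. Liver is the background tissue.
LABELS <- c(
  liver = 1L, tumor = 2L, vessel_wall = 3L, blood = 4L,
  electrode_active = 5L, electrode_insulated = 6L
)

#' Voxelized labeled scene
#'
#' A `label_scene` is the voxel-grid domain every other module operates on:
#' a 3-D integer array of tissue/electrode codes plus grid metadata. World
#' coordinates are in mm; `origin` is the world position of the center of
#' voxel `[1,1,1]`; voxel-center membership decides labels.
#'
#' @param labels 3-D integer array of label codes (see `scene_roles()`).
#' @param spacing Voxel edge lengths in mm (length 1 or 3).
#' @param origin World coordinates (mm) of the first voxel center.
#' @param meta Optional list of provenance metadata (tumor diameter, vessel
#'   geometry, ...) carried along for downstream modules.
#' @return An object of class `label_scene`.
#' @export
label_scene <- function(labels, spacing, origin, meta = list()) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(LABELS))
  if (length(bad))
    stop("unknown label code(s) in scene: ", paste(bad, collapse = ", "))
  structure(
    list(labels = labels, spacing = as.numeric(spacing),
         origin = as.numeric(origin), meta = meta),
    class = "label_scene"
  )
}

#' Role map of label codes
#'
#' @return Named integer vector mapping role names to label codes.
#' @export
scene_roles <- function() LABELS

#' Voxel-center coordinate axes of a scene
#'
#' @param scene A [label_scene()].
#' @return List with numeric vectors `x`, `y`, `z` of voxel-center world
#'   coordinates (mm).
#' @export
scene_axes <- function(scene) {
  d <- dim(scene$labels)
  list(
    x = scene$origin[1] + (seq_len(d[1]) - 1) * scene$spacing[1],
    y = scene$origin[2] + (seq_len(d[2]) - 1) * scene$spacing[2],
    z = scene$origin[3] + (seq_len(d[3]) - 1) * scene$spacing[3]
  )
}

#' @export
print.label_scene <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_scene %d x %d x %d voxels, spacing %s mm>\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = " x ")))
  tab <- table(factor(as.vector(x$labels), levels = unname(LABELS),
                      labels = names(LABELS)))
  vv <- prod(x$spacing)
  for (n in names(tab))
    if (tab[[n]] > 0)
      cat(sprintf("  %-19s %9d voxels  %10.1f mm^3\n", n, tab[[n]], tab[[n]] * vv))
  invisible(x)
}

#' Voxel volume of a scene (mm^3)
#' @param scene A [label_scene()].
#' @export
voxel_volume <- function(scene) prod(scene$spacing)

# logical mask for a role name (or several)
scene_mask <- function(scene, roles) {
  codes <- LABELS[roles]
  if (anyNA(codes)) stop("unknown role(s): ", paste(roles[is.na(codes)], collapse = ", "))
  array(scene$labels %in% codes, dim = dim(scene$labels))
}

# world -> fractional voxel index (1-based)
world_to_index <- function(scene, p) {
  (p - scene$origin) / scene$spacing + 1
}
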