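#' Treatment target fields (V/cm)
#'
#' The field magnitude a tissue volume must experience for the treatment
#' to be effective: 400 V/cm for electrochemotherapy (with its typical 8
#' pulses) and 600 V/cm for irreversible electroporation (90 pulses). The
#' irreversible threshold used for quantifying collateral exposure of
#' liver parenchyma is 400 V/cm.
#'
#' @param treatment `"ECT"` or `"IRE"`.
#' @return Target field in V/cm.
#' @export
target_field <- function(treatment = c("ECT", "IRE")) {
  switch(match.arg(treatment), ECT = 400, IRE = 600)
}

LIVER_IRE_THRESHOLD <- 400   # V/cm
SUCCESS_COVERAGE <- 99.9     # % of tumor volume

#' Tumor coverage and collateral-exposure report
#'
#' Computes the percentage of tumor volume whose field envelope meets or
#' exceeds the treatment's target field (400 V/cm for ECT, 600 V/cm for
#' IRE; ties at the threshold count as covered), the volume of liver
#' parenchyma above the liver IRE threshold (400 V/cm), and carries the
#' per-drive currents. A treatment is deemed successful when coverage is
#' at least 99.9%.
#'
#' @param envelope A [solve_sequence()] `field_envelope`.
#' @param scene The [label_scene()] the envelope was solved on.
#' @param treatment `"ECT"` or `"IRE"`.
#' @return An object of class `coverage_report`: list with `coverage_pct`,
#'   `target_field`, `liver_ire_volume_mm3`, `currents`, `success`.
#' @export
coverage <- function(envelope, scene, treatment = c("ECT", "IRE")) {
  treatment <- match.arg(treatment)
  if (!identical(dim(scene$labels), envelope$dims))
    stop("envelope and scene grids differ")
  tmask <- scene_mask(scene, "tumor")
  nt <- sum(tmask)
  if (nt == 0) stop("scene has no tumor voxels")
  tf <- target_field(treatment)
  cov <- 100 * sum(envelope$E_max[tmask] >= tf) / nt
  lmask <- scene_mask(scene, "liver")
  lvol <- sum(envelope$E_max[lmask] >= LIVER_IRE_THRESHOLD) * voxel_volume(scene)
  structure(
    list(coverage_pct = cov, target_field = tf,
         liver_ire_volume_mm3 = lvol,
         currents = envelope$currents,
         success = cov >= SUCCESS_COVERAGE,
         treatment = treatment,
         tumor_voxels = nt),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report %s>  coverage %.2f%% at %g V/cm (%s), liver >=400 V/cm: %.0f mm^3\n",
              x$treatment, x$coverage_pct, x$target_field,
              if (x$success) "success" else "insufficient",
              x$liver_ire_volume_mm3))
  invisible(x)
}

#' Check per-drive currents against the generator limit
#'
#' Clinical ECT/IRE pulse generators abort a pulse when the delivered
#' current exceeds their hardware limit (50 A for the devices considered
#' here); drives above the limit therefore fail.
#'
#' @param envelope A `field_envelope` (or `coverage_report`) carrying
#'   per-drive currents.
#' @param limit Current limit in A (default 50).
#' @return The `currents` data.frame with an added logical column `pass`.
#' @export
current_check <- function(envelope, limit = 50) {
  cur <- envelope$currents
  if (is.null(cur)) stop("no per-drive currents recorded")
  cur$pass <- cur$current_A <= limit
  cur
}
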