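#' Vessel-neglect robustness study on simplified models
#'
#' Reproduces the two-stage workflow of the simplified study: voltages are
#' first fixed on the vessel-free model (either supplied, taken from
#' [builtin_voltage_table()], or re-optimized), then the vessel is
#' introduced and the field is re-solved at those voltages. The drop in
#' tumor coverage quantifies the error made by ignoring the vessel during
#' treatment planning.
#'
#' @param tumor_diameter Tumor diameter (mm).
#' @param treatment `"ECT"` or `"IRE"`.
#' @param n_electrodes 4, 5 or 7 (must match a supported layout).
#' @param vessel_diameters,distances,orientations Study grid of vessel
#'   configurations.
#' @param voltages Either `NULL` (look up [builtin_voltage_table()]), a
#'   list/row with `U_outer` and `U_diag`, or `"optimize"` to re-optimize
#'   on the vessel-free scene.
#' @param spacing,padding Scene discretization parameters (mm).
#' @param tissues Tissue table.
#' @param control A [solver_control()].
#' @param depth_override Shallow-insertion overshoot (mm) for the
#'   small-tumor / large-perpendicular-vessel cells.
#' @param ... Passed to [optimize_voltages()] when `voltages = "optimize"`.
#' @return data.frame with one row per study cell: vessel geometry, the
#'   voltages used, tumor coverage, liver IRE volume, maximum drive
#'   current, success flag, and an `error` column for failed cells.
#' @export
run_ignore_vessel_study <- function(tumor_diameter, treatment, n_electrodes,
                                    vessel_diameters = c(1, 3, 5, 7, 10, 15),
                                    distances = c(0, 1, 3, 5, 10),
                                    orientations = c("perpendicular", "parallel"),
                                    voltages = NULL,
                                    spacing = 0.5, padding = 10,
                                    tissues = builtin_tissue_table(),
                                    control = solver_control(),
                                    depth_override = 1, ...) {
  if (is.null(voltages)) {
    vt <- builtin_voltage_table()
    row <- vt[vt$tumor_diameter == tumor_diameter & vt$treatment == treatment &
                vt$n_electrodes == n_electrodes, ]
    if (nrow(row) != 1)
      stop("no reference voltages for this configuration; pass `voltages`")
    voltages <- list(U_outer = row$U_outer, U_diag = row$U_diag)
  } else if (identical(voltages, "optimize")) {
    sc0 <- build_simplified_scene(tumor_diameter, spacing = spacing,
                                  padding = padding)
    el0 <- place_electrodes(sc0, treatment, n_electrodes,
                            depth_override = depth_override)
    sc0 <- rasterize_electrodes(sc0, el0)
    opt <- optimize_voltages(sc0, treatment, tissues = tissues,
                             control = control, ...)
    voltages <- list(U_outer = opt$U_outer, U_diag = opt$U_diag)
  }

  grid <- expand.grid(vessel_diameter = vessel_diameters, distance = distances,
                      orientation = orientations, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    vd <- grid$vessel_diameter[g]; dd <- grid$distance[g]
    orient <- grid$orientation[g]
    rows[[g]] <- tryCatch({
      sc <- suppressWarnings(build_simplified_scene(
        tumor_diameter, vessel_diameter = vd, distance = dd,
        orientation = orient, spacing = spacing, padding = padding))
      el <- place_electrodes(sc, treatment, n_electrodes,
                             depth_override = depth_override)
      sc <- rasterize_electrodes(sc, el)
      plan <- make_pulse_plan(el, voltages$U_outer, voltages$U_diag)
      env <- solve_sequence(sc, plan, tissues, control)
      rep <- coverage(env, sc, treatment)
      shallow <- el[[1]]$tip_lo > -sc$meta$tip_length / 2 + 1e-9
      data.frame(tumor_diameter = tumor_diameter, treatment = treatment,
                 n_electrodes = n_electrodes, vessel_diameter = vd,
                 distance = dd, orientation = orient,
                 U_outer = voltages$U_outer, U_diag = voltages$U_diag,
                 coverage_pct = rep$coverage_pct,
                 liver_ire_volume_mm3 = rep$liver_ire_volume_mm3,
                 max_current_A = max(env$currents$current_A),
                 tumor_voxels = rep$tumor_voxels,
                 success = rep$success, depth_override_applied = shallow,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(tumor_diameter = tumor_diameter, treatment = treatment,
                 n_electrodes = n_electrodes, vessel_diameter = vd,
                 distance = dd, orientation = orient,
                 U_outer = voltages$U_outer, U_diag = voltages$U_diag,
                 coverage_pct = NA_real_, liver_ire_volume_mm3 = NA_real_,
                 max_current_A = NA_real_, tumor_voxels = NA_integer_,
                 success = NA, depth_override_applied = NA,
                 error = conditionMessage(e))
    })
  }
  do.call(rbind, rows)
}

# optimize on a (possibly perturbed) planning scene, evaluate on the true
# scene with the same electrodes
optimize_then_evaluate <- function(plan_scene, true_scene, electrodes,
                                   treatment, tissues, control, ...) {
  res <- resolve_electrode_vessel_collisions(plan_scene, electrodes)
  plan_sc <- rasterize_electrodes(plan_scene, res$electrodes)
  opt <- optimize_voltages(plan_sc, treatment, tissues = tissues,
                           control = control, ...)
  true_sc <- rasterize_electrodes(true_scene, res$electrodes)
  plan <- make_pulse_plan(res$electrodes, opt$U_outer, opt$U_diag)
  env <- solve_sequence(true_sc, plan, tissues, control)
  rep <- coverage(env, true_sc, treatment)
  list(opt = opt, report = rep, env = env, collisions = res$report)
}

#' Segmentation-error robustness study
#'
#' Emulates the effect of automatic vessel-segmentation errors on
#' treatment planning: the vessel mask of the scene is perturbed by each
#' of the six transformations (enlarge, shrink, four in-plane shifts) at
#' each error magnitude, electrode positions are minimally adjusted if the
#' perturbed vessel would be punctured, voltages are optimized on the
#' perturbed scene, and the resulting plan is evaluated on the scene with
#' the true vessel geometry. A magnitude-0 baseline (optimize on the true
#' scene) is included per layout.
#'
#' @param scene A [label_scene()] with a vessel (e.g.
#'   [build_patient_like_scene()]).
#' @param n_electrodes_list Electrode layouts to compare (default with and
#'   without the central electrode).
#' @param magnitudes Error magnitudes in pixels (default 1 = average
#'   error, 3 = maximum error).
#' @param kinds Subset of the six transformations.
#' @param treatment Treatment type (the real-patient workflow uses ECT).
#' @param px_mm Pixel size of the segmented image (mm).
#' @param tissues,control,... As in [optimize_voltages()].
#' @return data.frame with one row per layout x transformation x
#'   magnitude: optimized voltages, coverage on the true geometry, breach
#'   flags, success, and an `error` column for degenerate cells.
#' @export
run_segmentation_error_study <- function(scene,
                                         n_electrodes_list = c(5L, 4L),
                                         magnitudes = c(1, 3),
                                         kinds = c("enlarge", "shrink",
                                                   "shift_left", "shift_right",
                                                   "shift_up", "shift_down"),
                                         treatment = "ECT", px_mm = 1,
                                         tissues = builtin_tissue_table(),
                                         control = solver_control(), ...) {
  rows <- list()
  for (ne in n_electrodes_list) {
    el <- place_electrodes(scene, treatment, ne)
    cells <- c(list(list(kind = "none", magnitude = 0)),
               unlist(lapply(kinds, function(k) lapply(magnitudes, function(m)
                 list(kind = k, magnitude = m))), recursive = FALSE))
    for (cell in cells) {
      rows[[length(rows) + 1L]] <- tryCatch({
        plan_scene <- if (cell$magnitude == 0) scene else
          perturb_vessel(scene, perturbation_spec(cell$kind, cell$magnitude, px_mm))
        res <- optimize_then_evaluate(plan_scene, scene, el, treatment,
                                      tissues, control, ...)
        data.frame(n_electrodes = ne, transformation = cell$kind,
                   magnitude_px = cell$magnitude,
                   U_outer = res$opt$U_outer, U_diag = res$opt$U_diag,
                   coverage_pct = res$report$coverage_pct,
                   liver_ire_volume_mm3 = res$report$liver_ire_volume_mm3,
                   max_current_A = max(res$env$currents$current_A),
                   breach = any(res$collisions$breach),
                   success = res$report$success, error = NA_character_)
      }, error = function(e)
        data.frame(n_electrodes = ne, transformation = cell$kind,
                   magnitude_px = cell$magnitude, U_outer = NA_real_,
                   U_diag = NA_real_, coverage_pct = NA_real_,
                   liver_ire_volume_mm3 = NA_real_, max_current_A = NA_real_,
                   breach = NA, success = NA, error = conditionMessage(e)))
    }
  }
  do.call(rbind, rows)
}

#' Vessel-exclusion comparison study
#'
#' Quantifies the consequence of planning as if the vessels were not there
#' at all: vessels are relabeled as liver, voltages are optimized on that
#' vessel-free model, and the plan is evaluated on the true geometry.
#'
#' @inheritParams run_segmentation_error_study
#' @return data.frame with one row per layout.
#' @export
run_no_vessel_comparison <- function(scene, n_electrodes_list = c(5L, 4L),
                                     treatment = "ECT",
                                     tissues = builtin_tissue_table(),
                                     control = solver_control(), ...) {
  novessel <- scene
  vmask <- scene_mask(scene, c("vessel_wall", "blood"))
  novessel$labels[vmask] <- LABELS[["liver"]]
  novessel$meta$vessel <- NULL
  rows <- list()
  for (ne in n_electrodes_list) {
    el <- place_electrodes(scene, treatment, ne)
    rows[[length(rows) + 1L]] <- tryCatch({
      res <- optimize_then_evaluate(novessel, scene, el, treatment,
                                    tissues, control, ...)
      data.frame(n_electrodes = ne,
                 U_outer = res$opt$U_outer, U_diag = res$opt$U_diag,
                 coverage_planned_pct = res$opt$coverage_pct,
                 coverage_true_pct = res$report$coverage_pct,
                 liver_ire_volume_mm3 = res$report$liver_ire_volume_mm3,
                 success = res$report$success, error = NA_character_)
    }, error = function(e)
      data.frame(n_electrodes = ne, U_outer = NA_real_, U_diag = NA_real_,
                 coverage_planned_pct = NA_real_, coverage_true_pct = NA_real_,
                 liver_ire_volume_mm3 = NA_real_, success = NA,
                 error = conditionMessage(e)))
  }
  do.call(rbind, rows)
}
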