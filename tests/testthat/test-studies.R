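# Study orchestration is exercised on deliberately coarse grids (2-2.5 mm
# spacing, reduced study cells) so the suite stays fast; the physical
# direction-of-effect assertions on denser grids live with the acceptance
# checks.

test_that("ignore-vessel study emits a schema-stable, deterministic table", {
  tab <- run_ignore_vessel_study(10, "ECT", 4L,
                                 vessel_diameters = c(3, 7),
                                 distances = c(0, 5),
                                 orientations = c("perpendicular", "parallel"),
                                 spacing = 2, padding = 4)
  expect_equal(nrow(tab), 8)
  expect_true(all(c("vessel_diameter", "distance", "orientation", "U_outer",
                    "U_diag", "coverage_pct", "liver_ire_volume_mm3",
                    "max_current_A", "success", "error") %in% names(tab)))
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$coverage_pct >= 0 & tab$coverage_pct <= 100))
  # reference voltages for this configuration were looked up
  expect_equal(unique(tab$U_outer), 600)
  expect_equal(unique(tab$U_diag), 1000)
  tab2 <- run_ignore_vessel_study(10, "ECT", 4L,
                                  vessel_diameters = c(3, 7),
                                  distances = c(0, 5),
                                  orientations = c("perpendicular", "parallel"),
                                  spacing = 2, padding = 4)
  expect_identical(tab, tab2)
})

test_that("ignore-vessel rows are recomputable from their logged voltages", {
  tab <- run_ignore_vessel_study(10, "ECT", 4L, vessel_diameters = 7,
                                 distances = 0, orientations = "parallel",
                                 spacing = 2, padding = 4)
  sc <- suppressWarnings(build_simplified_scene(10, vessel_diameter = 7,
                                                distance = 0,
                                                orientation = "parallel",
                                                spacing = 2, padding = 4))
  res <- solve_case(sc, "ECT", 4L, tab$U_outer[1], tab$U_diag[1])
  expect_equal(res$report$coverage_pct, tab$coverage_pct[1])
})

test_that("depth override is applied exactly for the anomaly cells", {
  tab <- run_ignore_vessel_study(10, "ECT", 4L,
                                 vessel_diameters = c(7, 10),
                                 distances = 0,
                                 orientations = c("perpendicular", "parallel"),
                                 spacing = 2, padding = 4)
  ov <- tab$depth_override_applied
  expect_identical(ov[tab$vessel_diameter == 10 & tab$orientation == "perpendicular"], TRUE)
  expect_identical(unique(ov[tab$vessel_diameter == 7]), FALSE)
  expect_identical(unique(ov[tab$orientation == "parallel"]), FALSE)
})

seg_scene <- function() build_patient_like_scene(1, spacing = 2.5, padding = 6)

test_that("segmentation-error study mirrors the perturb-optimize-evaluate workflow", {
  sc <- seg_scene()
  tab <- run_segmentation_error_study(
    sc, n_electrodes_list = 5L, magnitudes = 1,
    kinds = c("shrink", "shift_right"),
    bounds = c(600, 1800), step = 600)
  expect_equal(nrow(tab), 3)  # baseline + two transformations
  expect_true(all(is.na(tab$error)))
  base <- tab[tab$transformation == "none", ]
  expect_equal(base$magnitude_px, 0)
  # magnitude-0 equals plain optimization on the true scene
  el <- place_electrodes(sc, "ECT", 5L)
  sc_r <- rasterize_electrodes(sc, el)
  opt <- optimize_voltages(sc_r, "ECT", bounds = c(600, 1800), step = 600)
  expect_equal(base$U_outer, opt$U_outer)
  expect_equal(base$coverage_pct, opt$coverage_pct)
})

test_that("degenerate perturbations are flagged but the study continues", {
  sc <- coarse_scene(10, vessel_diameter = 3, distance = 2,
                     orientation = "parallel", spacing = 1, padding = 4)
  tab <- run_segmentation_error_study(
    sc, n_electrodes_list = 4L, magnitudes = 3, kinds = c("shrink"),
    treatment = "ECT", bounds = c(600, 600), step = 600)
  bad <- tab[tab$transformation == "shrink", ]
  expect_false(is.na(bad$error))
  expect_match(bad$error, "degenerate|eliminates")
  expect_true(is.na(bad$coverage_pct))
  # baseline row still computed
  expect_true(is.na(tab$error[tab$transformation == "none"]))
})

test_that("no-vessel comparison optimizes without vessels, evaluates with them", {
  sc <- seg_scene()
  tab <- run_no_vessel_comparison(sc, n_electrodes_list = c(5L, 4L),
                                  bounds = c(600, 1800), step = 600)
  expect_equal(nrow(tab), 2)
  expect_true(all(is.na(tab$error)))
  # planned coverage (without vessel) is at least the true coverage minus
  # numerical slack: the vessel can only sink field, not add it
  expect_true(all(tab$coverage_true_pct <= tab$coverage_planned_pct + 0.5))
  tab2 <- run_no_vessel_comparison(sc, n_electrodes_list = c(5L, 4L),
                                   bounds = c(600, 1800), step = 600)
  expect_identical(tab, tab2)
})
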