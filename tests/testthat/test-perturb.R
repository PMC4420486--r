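base_vessel_scene <- function(spacing = 1) {
  coarse_scene(10, vessel_diameter = 6, distance = 2, orientation = "parallel",
               spacing = spacing, padding = 4)
}

test_that("zero-magnitude perturbations are the identity", {
  sc <- base_vessel_scene()
  for (k in c("enlarge", "shrink", "shift_left", "shift_up")) {
    p <- perturb_vessel(sc, perturbation_spec(k, 0))
    expect_identical(p$labels, sc$labels)
  }
})

test_that("shift left then right restores the vessel mask exactly", {
  sc <- base_vessel_scene()
  vm0 <- scene_mask(sc, c("vessel_wall", "blood"))
  p <- perturb_vessel(sc, perturbation_spec("shift_left", 2))
  expect_false(identical(scene_mask(p, c("vessel_wall", "blood")), vm0))
  q <- perturb_vessel(p, perturbation_spec("shift_right", 2))
  expect_identical(scene_mask(q, c("vessel_wall", "blood")), vm0)
  # displaced voxels became liver, not anything else
  expect_true(all(p$labels[vm0 & !scene_mask(p, c("vessel_wall", "blood"))] ==
                    scene_roles()[["liver"]]))
})

test_that("enlarge/shrink change voxel counts like morphological dilation/erosion", {
  skip_if_not_installed("EBImage")
  sc <- base_vessel_scene()
  vm <- scene_mask(sc, c("vessel_wall", "blood"))
  for (m in c(1, 3)) {
    grown <- scene_mask(perturb_vessel(sc, perturbation_spec("enlarge", m)),
                        c("vessel_wall", "blood"))
    shrunk <- scene_mask(perturb_vessel(sc, perturbation_spec("shrink", m)),
                         c("vessel_wall", "blood"))
    # independent oracle: EBImage 2-D morphology applied slice by slice,
    # with an explicit euclidean-disk kernel
    off <- expand.grid(dx = -m:m, dy = -m:m)
    brush <- matrix(as.numeric(off$dx^2 + off$dy^2 <= m^2 + 1e-9),
                    2 * m + 1, 2 * m + 1)
    ref_grow <- array(FALSE, dim = dim(vm))
    ref_shrink <- array(FALSE, dim = dim(vm))
    for (k in seq_len(dim(vm)[3])) {
      ref_grow[, , k] <- EBImage::dilate(vm[, , k] * 1, brush) > 0
      ref_shrink[, , k] <- EBImage::erode(vm[, , k] * 1, brush) > 0
    }
    expect_identical(grown, ref_grow)
    expect_identical(shrunk, ref_shrink)
    expect_gt(sum(grown), sum(vm))
    expect_lt(sum(shrunk), sum(vm))
  }
  # enlarge then shrink returns to the morphological closing of the vessel,
  # which for a convex cylinder cross-section is (close to) the original
  p <- perturb_vessel(sc, perturbation_spec("enlarge", 1))
  q <- perturb_vessel(p, perturbation_spec("shrink", 1))
  n0 <- sum(vm)
  n1 <- sum(scene_mask(q, c("vessel_wall", "blood")))
  expect_lt(abs(n1 - n0) / n0, 0.15)
})

test_that("perturbation magnitudes honor the pixel size", {
  sc <- base_vessel_scene(spacing = 0.5)
  vm <- scene_mask(sc, c("vessel_wall", "blood"))
  # 1 px at 1 mm/px on a 0.5 mm grid shifts by 2 voxels
  p <- perturb_vessel(sc, perturbation_spec("shift_right", 1, px_mm = 1))
  idx0 <- which(vm, arr.ind = TRUE)
  idx1 <- which(scene_mask(p, c("vessel_wall", "blood")), arr.ind = TRUE)
  expect_equal(mean(idx1[, 1]) - mean(idx0[, 1]), 2, tolerance = 1e-6)
})

test_that("degenerate erosion is reported as an error", {
  sc <- coarse_scene(10, vessel_diameter = 3, distance = 2,
                     orientation = "parallel")
  expect_error(perturb_vessel(sc, perturbation_spec("shrink", 3)),
               "degenerate|eliminates")
  expect_error(perturb_vessel(coarse_scene(10),
                              perturbation_spec("enlarge", 1)),
               "no vessel")
})

test_that("collision resolution moves electrodes off the vessel or flags breach", {
  # vessel parallel to the electrodes and straddling one electrode axis
  sc <- coarse_scene(10, vessel_diameter = 6, distance = 0,
                     orientation = "parallel", spacing = 0.5, padding = 4)
  el <- place_electrodes(sc, "ECT", 4L)
  # electrode 1 sits at (4.95, 4.95); vessel axis at x = 8, y = 0: no hit
  res0 <- resolve_electrode_vessel_collisions(sc, el)
  expect_false(any(res0$report$collided))
  expect_identical(res0$electrodes, el)

  # force a collision: put an electrode straight through the vessel
  bad <- el
  bad[[1]]$x <- sc$meta$vessel$center[1]
  bad[[1]]$y <- 0
  res <- resolve_electrode_vessel_collisions(sc, bad)
  expect_true(res$report$collided[1])
  expect_true(res$report$moved[1])
  expect_false(res$report$breach[1])
  # exhaustive-search oracle: 3 mm outer radius + clearance, so the
  # smallest clearing offset cannot exceed ~4 mm
  expect_lte(res$report$offset_mm[1], 4)
  # and the moved electrode really is clear of the vessel
  sc2 <- rasterize_electrodes(sc, res$electrodes)
  expect_false(any(scene_mask(sc2, "electrode_active") &
                     scene_mask(sc, c("vessel_wall", "blood"))))

  # a vessel much wider than the search cap is an unavoidable breach
  sc_big <- coarse_scene(10, vessel_diameter = 15, distance = 0,
                         orientation = "parallel", spacing = 1, padding = 4)
  elb <- place_electrodes(sc_big, "IRE", 4L)
  elb[[1]]$x <- sc_big$meta$vessel$center[1]
  elb[[1]]$y <- 0
  resb <- resolve_electrode_vessel_collisions(sc_big, elb, max_offset = 2)
  expect_true(resb$report$breach[1])
  expect_equal(resb$electrodes[[1]]$x, elb[[1]]$x)  # kept in place
})
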