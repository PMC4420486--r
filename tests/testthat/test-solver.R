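# Verification of the finite-volume solver against closed forms, plus the
# physical invariants of the pulse-sequence machinery.

fv_solve <- ectfield:::.fv_solve

test_that("1-D layered slab matches the series-resistor closed form exactly", {
  # three material layers along z, unit cross-section, driven end to end
  h <- c(1, 1, 1)
  sig_layers <- c(0.04, 0.2, 0.7)
  n_per <- 5L
  sigma <- rep(sig_layers, each = n_per)
  N <- length(sigma)
  dims <- c(1L, 1L, N)
  V <- 100
  fixed <- integer(N); fixed[1] <- 1L; fixed[N] <- 1L
  fixedval <- numeric(N); fixedval[1] <- V / 2; fixedval[N] <- -V / 2
  sol <- fv_solve(dims, h, sigma, fixed, fixedval, numeric(N),
                  tol = 1e-13, maxit = 1000)
  phi <- sol$phi

  # independent oracle: resistor chain with harmonic-mean face conductances
  g <- 2 * sigma[-N] * sigma[-1] / (sigma[-N] + sigma[-1]) * 1e-3  # S
  R_tot <- sum(1 / g)
  I <- V / R_tot
  phi_exact <- V / 2 - c(0, cumsum(I / g))
  expect_equal(phi, phi_exact, tolerance = 1e-10)

  # discrete current conservation: flux through every face is identical
  flux <- g * (phi[-N] - phi[-1])
  expect_equal(flux, rep(I, N - 1), tolerance = 1e-9 * I)
})

test_that("concentric-cylinder annulus matches the ln(r) closed form within 2%", {
  # homogeneous conductor between two coaxial cylindrical electrodes; radii
  # large relative to the voxel size so the staircased electrode surfaces
  # perturb the effective radii by well under the comparison tolerance
  a <- 5; b <- 16; V <- 100
  h <- 0.25
  n <- 2 * ceiling(b / h) + 3
  ax <- (seq_len(n) - (n + 1) / 2) * h
  r <- sqrt(outer(ax^2, ax^2, "+"))
  dims <- c(n, n, 3L)
  rr <- array(rep(r, 3), dim = dims)
  sigma <- rep(0.1, prod(dims))
  fixed <- integer(prod(dims))
  fixedval <- numeric(prod(dims))
  fixed[rr <= a] <- 1L; fixedval[rr <= a] <- V / 2
  fixed[rr >= b] <- 1L; fixedval[rr >= b] <- -V / 2
  sol <- fv_solve(dims, c(h, h, h), sigma, fixed, fixedval,
                  numeric(prod(dims)), tol = 1e-10, maxit = 5000)
  phi <- array(sol$phi, dim = dims)[, , 2]
  exact <- function(r) V / 2 - V * log(r / a) / log(b / a)
  # compare away from both electrode surfaces
  sel <- r > a + 2 * h & r < b - 2 * h
  err <- abs(phi[sel] - exact(r[sel])) / V
  expect_lt(max(err), 0.02)
})

test_that("zero-voltage drive gives a null field and zero current", {
  cs <- coarse_scene(10, spacing = 1.5, padding = 4)
  el <- place_electrodes(cs, "ECT", 4L)
  sc <- rasterize_electrodes(cs, el)
  sol <- solve_drive(sc, list(anode = 1L, cathode = 2L, voltage = 0))
  expect_true(all(sol$phi == 0))
  expect_true(all(sol$E == 0))
  expect_equal(sol$current, 0)
})

test_that("swapping anode and cathode negates the potential, preserves |E| and current", {
  cs <- coarse_scene(10, spacing = 1.5, padding = 4)
  el <- place_electrodes(cs, "ECT", 4L)
  sc <- rasterize_electrodes(cs, el)
  ctrl <- solver_control(picard_max = 0)  # one linear iterate
  s1 <- solve_drive(sc, list(anode = 1L, cathode = 3L, voltage = 500), control = ctrl)
  s2 <- solve_drive(sc, list(anode = 3L, cathode = 1L, voltage = 500), control = ctrl)
  expect_equal(s2$phi, -s1$phi, tolerance = 1e-6)
  expect_equal(s2$E, s1$E, tolerance = 1e-6)
  expect_equal(s2$current, s1$current, tolerance = 1e-6)
})

test_that("currents balance between anode and cathode to solver tolerance", {
  cs <- coarse_scene(10, spacing = 1, padding = 5)
  res <- solve_case(cs, "ECT", 4L, 600, 1000)
  cur <- res$env$currents
  expect_true(all(cur$imbalance_A < 1e-3 * cur$current_A))
  expect_true(all(cur$converged))
})

test_that("field envelope accumulates the pointwise maximum with monotone conductivity", {
  cs <- coarse_scene(10, spacing = 1.5, padding = 4)
  el <- place_electrodes(cs, "ECT", 4L)
  sc <- rasterize_electrodes(cs, el)
  tt <- builtin_tissue_table()

  # single drive: envelope equals that drive's field
  plan1 <- make_pulse_plan(el, 600, 1000)[1, ]
  env1 <- solve_sequence(sc, plan1, tt)
  s1 <- solve_drive(sc, plan1[1, ], tt)
  expect_equal(env1$E_max, s1$E, tolerance = 1e-8)

  # two identical consecutive drives: the state has converged, so the
  # second field equals the first within the Picard tolerance
  plan2 <- rbind(plan1, plan1)
  class(plan2) <- c("pulse_plan", "data.frame")
  env2 <- solve_sequence(sc, plan2, tt)
  expect_equal(env2$E_max, env1$E_max, tolerance = 5e-3)

  # sigma state lies within each tissue's [sigma0, sigma1] band
  full <- make_pulse_plan(el, 600, 1000)
  env <- solve_sequence(sc, full, tt)
  for (tis in c("liver", "tumor")) {
    m <- sc$labels == scene_roles()[[tis]]
    expect_true(all(env$sigma[m] >= tt[[tis]]$sigma0 - 1e-12))
    expect_true(all(env$sigma[m] <= tt[[tis]]$sigma1 + 1e-12))
  }
  expect_true(all(env$E_max >= 0))
  # conductivity memory: re-running the first drive after the full plan
  # cannot lower any voxel's conductivity state
  sig_seq <- ectfield:::sigma_from_field(sc, env$E_max, tt)
  sig_one <- ectfield:::sigma_from_field(sc, env1$E_max, tt)
  expect_true(all(sig_seq - sig_one >= -1e-12))
})

test_that("raising a drive voltage never lowers the envelope (monotone load)", {
  cs <- coarse_scene(10, spacing = 1.5, padding = 4)
  el <- place_electrodes(cs, "ECT", 4L)
  sc <- rasterize_electrodes(cs, el)
  # with field-independent conductivity the drives superpose per pair and
  # the envelope is exactly monotone in every drive voltage
  tt_lin <- linear_tissues(c(liver = 0.04, tumor = 0.2,
                             vessel_wall = 0.26, blood = 0.7))
  lo <- solve_sequence(sc, make_pulse_plan(el, 500, 800), tt_lin)
  hi <- solve_sequence(sc, make_pulse_plan(el, 600, 800), tt_lin)
  expect_true(all(hi$E_max - lo$E_max >= -1e-9 * max(hi$E_max)))
  # with electroporation-dependent conductivity the extra conductivity
  # raised by the higher drive redistributes the other drives' fields, so
  # per-voxel monotonicity holds only up to a small second-order effect
  lo_nl <- solve_sequence(sc, make_pulse_plan(el, 500, 800))
  hi_nl <- solve_sequence(sc, make_pulse_plan(el, 600, 800))
  expect_true(all(hi_nl$E_max - lo_nl$E_max >= -0.05 * max(hi_nl$E_max)))
})

test_that("drive order does not change the treatment-relevant coverage", {
  cs <- coarse_scene(10, spacing = 1.5, padding = 4)
  el <- place_electrodes(cs, "ECT", 4L)
  sc <- rasterize_electrodes(cs, el)
  plan <- make_pulse_plan(el, 600, 1000)
  fwd <- solve_sequence(sc, plan)
  rev_plan <- plan[rev(seq_len(nrow(plan))), ]
  class(rev_plan) <- c("pulse_plan", "data.frame")
  bwd <- solve_sequence(sc, rev_plan)
  # the conductivity-memory path makes the per-voxel envelope mildly order
  # dependent, but the coverage metric must be insensitive
  expect_equal(coverage(fwd, sc, "ECT")$coverage_pct,
               coverage(bwd, sc, "ECT")$coverage_pct, tolerance = 2e-3)
  tmask <- scene_mask(sc, "tumor")
  diff_rel <- max(abs(fwd$E_max[tmask] - bwd$E_max[tmask])) / max(fwd$E_max[tmask])
  expect_lt(diff_rel, 0.10)
})

test_that("coverage is insensitive to the liver padding margin", {
  cov <- vapply(c(5, 10), function(pad) {
    cs <- coarse_scene(10, spacing = 1.5, padding = pad)
    solve_case(cs, "ECT", 4L, 600, 1000)$report$coverage_pct
  }, 0)
  expect_lt(abs(cov[1] - cov[2]), 0.5)
})

test_that("degenerate solver inputs raise informative errors", {
  cs <- coarse_scene(10, spacing = 1.5, padding = 4)
  expect_error(solve_drive(cs, list(anode = 1L, cathode = 2L, voltage = 100)),
               "no rasterized electrodes")
  el <- place_electrodes(cs, "ECT", 4L)
  sc <- rasterize_electrodes(cs, el)
  expect_error(solve_drive(sc, list(anode = 1L, cathode = 9L, voltage = 100)),
               "unknown electrode")
})
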