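# Small scenes and controls shared across tests. Coarse spacing keeps the
# suite fast; solver-accuracy checks have their own dedicated fixtures.

coarse_scene <- function(tumor_diameter = 10, ..., spacing = 1, padding = 5) {
  suppressWarnings(build_simplified_scene(tumor_diameter, ...,
                                          spacing = spacing, padding = padding))
}

fast_control <- function(...) solver_control(cg_tol = 1e-7, ...)

# linear (field-independent) tissue table: sigma1 == sigma0
linear_tissues <- function(sigma = c(liver = 0.1, tumor = 0.1,
                                     vessel_wall = 0.1, blood = 0.1)) {
  builtin_tissue_table(overrides = lapply(as.list(sigma), function(s)
    list(sigma0 = s, sigma1 = s)))
}

solve_case <- function(scene, treatment, n_electrodes, U_outer, U_diag,
                       tissues = builtin_tissue_table(),
                       control = fast_control(), ...) {
  el <- place_electrodes(scene, treatment, n_electrodes, ...)
  sc <- rasterize_electrodes(scene, el)
  plan <- make_pulse_plan(el, U_outer, U_diag)
  env <- solve_sequence(sc, plan, tissues, control)
  list(scene = sc, electrodes = el, plan = plan, env = env,
       report = coverage(env, sc, treatment))
}
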