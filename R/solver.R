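#' Solver control settings
#'
#' @param cg_tol Relative-residual tolerance of the conjugate-gradient
#'   linear solver.
#' @param cg_maxit Maximum CG iterations.
#' @param picard_tol Relative conductivity-change tolerance of the
#'   nonlinear fixed-point iteration.
#' @param picard_max Maximum Picard iterations per drive (0 = one linear
#'   solve at the current conductivity state).
#' @param relax Under-relaxation factor applied to conductivity updates.
#' @param sigma_metal Conductivity (S/m) assigned to electrode metal;
#'   large versus tissue so active tips are near-equipotential even when
#'   not driven.
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(cg_tol = 1e-6, cg_maxit = 20000,
                           picard_tol = 1e-3, picard_max = 50,
                           relax = 0.5, sigma_metal = 50) {
  structure(list(cg_tol = cg_tol, cg_maxit = cg_maxit,
                 picard_tol = picard_tol, picard_max = picard_max,
                 relax = relax, sigma_metal = sigma_metal),
            class = "solver_control")
}

# linear voxel indices of an electrode's active tip
electrode_cells <- function(scene, e) {
  axs <- scene_axes(scene)
  d <- dim(scene$labels)
  cols <- electrode_columns(scene, e)
  kz <- which(axs$z >= e$tip_lo & axs$z <= e$tip_hi)
  out <- integer(0)
  for (r in seq_len(nrow(cols)))
    out <- c(out, cols[r, 1] + d[1] * (cols[r, 2] - 1 + d[2] * (kz - 1)))
  out
}

# per-voxel tissue conductivity (S/m) at field state E (V/cm); electrode
# voxels get placeholders that the solver overrides
sigma_from_field <- function(scene, E, tissues, masks = NULL) {
  if (is.null(masks)) masks <- tissue_masks(scene)
  sig <- array(0, dim = dim(scene$labels))
  for (tis in names(masks$tissue)) {
    m <- masks$tissue[[tis]]
    if (any(m)) sig[m] <- conductivity(E[m], tissues[[tis]])
  }
  sig
}

tissue_masks <- function(scene) {
  tn <- c("liver", "tumor", "vessel_wall", "blood")
  list(
    tissue = stats::setNames(lapply(tn, function(t) scene_mask(scene, t)), tn),
    active = scene_mask(scene, "electrode_active"),
    insulated = scene_mask(scene, "electrode_insulated")
  )
}

#' Solve one electrode-pair drive
#'
#' Solves the nonlinear electrostatic problem
#' `div(sigma(|grad phi|) grad phi) = 0` for a single pair drive: Dirichlet
#' potentials +V/2 / -V/2 on the anode/cathode active-tip voxels, no-flux
#' on the outer boundary, insulated shafts as non-conducting voxels, and
#' undriven electrodes as passive high-conductivity metal. The
#' conductivity is made self-consistent with the solved field by Picard
#' fixed-point iteration with under-relaxation; each voxel's conductivity
#' is evaluated at the maximum of the current field and the field memory
#' `E_mem` carried over from earlier drives (electroporation does not
#' reseal within a pulse train).
#'
#' @param scene A rasterized [label_scene()] (see [rasterize_electrodes()]).
#' @param drive One-row piece of a [make_pulse_plan()] plan (list/row with
#'   `anode`, `cathode`, `voltage`).
#' @param tissues Tissue table, see [builtin_tissue_table()].
#' @param E_mem Optional per-voxel field-memory array (V/cm).
#' @param control A [solver_control()].
#' @param phi0 Optional initial potential guess.
#' @return List with `phi` (V), `E` (V/cm), `current` (A, mean of anode and
#'   cathode magnitudes), `current_imbalance` (A), `picard_iterations`,
#'   `converged`, `sigma` (S/m tissue-state array used in the last solve).
#' @export
solve_drive <- function(scene, drive, tissues = builtin_tissue_table(),
                        E_mem = NULL, control = solver_control(), phi0 = NULL) {
  els <- scene$meta$electrodes
  if (is.null(els)) stop("scene has no rasterized electrodes")
  d <- dim(scene$labels)
  n <- prod(d)
  if (is.null(E_mem)) E_mem <- array(0, dim = d)
  if (is.null(phi0)) phi0 <- numeric(n)
  masks <- scene$meta$solver_masks %||% tissue_masks(scene)

  byid <- stats::setNames(els, vapply(els, function(e) as.character(e$id), ""))
  an <- byid[[as.character(drive$anode)]]
  ca <- byid[[as.character(drive$cathode)]]
  if (is.null(an) || is.null(ca)) stop("drive names unknown electrode id")
  an_cells <- electrode_cells(scene, an)
  ca_cells <- electrode_cells(scene, ca)

  fixed <- integer(n)
  fixedval <- numeric(n)
  fixed[an_cells] <- 1L; fixedval[an_cells] <- +drive$voltage / 2
  fixed[ca_cells] <- 1L; fixedval[ca_cells] <- -drive$voltage / 2

  sig_t <- sigma_from_field(scene, E_mem, tissues, masks)
  phi <- phi0
  E <- E_mem
  iters <- 0L
  cg_total <- 0L
  conv <- FALSE
  delta <- Inf
  repeat {
    sig_eff <- sig_t
    sig_eff[masks$active] <- control$sigma_metal
    sig_eff[masks$insulated] <- 0
    # inexact inner solves: while the conductivity state is still moving the
    # linear system only needs to be solved to a fraction of that movement;
    # the final solve (post-convergence) runs at the full tolerance
    inner_tol <- if (is.finite(delta) && delta >= control$picard_tol)
      min(1e-4, max(control$cg_tol, delta * 1e-2)) else control$cg_tol
    sol <- .fv_solve(dims = d, h = scene$spacing, sigma = as.vector(sig_eff),
                     fixed = fixed, fixedval = fixedval, phi0 = phi,
                     tol = inner_tol, maxit = control$cg_maxit)
    if (!sol$converged)
      stop("linear solver did not converge (relres = ", signif(sol$relres, 3), ")")
    phi <- sol$phi
    cg_total <- cg_total + sol$iterations
    E <- array(10 * .field_magnitude(phi, d, scene$spacing, as.vector(sig_eff)),
               dim = d)  # V/mm -> V/cm
    if (control$picard_max == 0L) { conv <- TRUE; break }
    sig_new <- sigma_from_field(scene, pmax(E_mem, E), tissues, masks)
    delta_new <- max(abs(sig_new - sig_t) / pmax(sig_t, 1e-12))
    sig_t <- sig_t + control$relax * (sig_new - sig_t)
    iters <- iters + 1L
    if (delta_new < control$picard_tol) {
      # converged; one more solve at the full tolerance
      delta <- delta_new
      sig_eff <- sig_t
      sig_eff[masks$active] <- control$sigma_metal
      sig_eff[masks$insulated] <- 0
      sol <- .fv_solve(dims = d, h = scene$spacing, sigma = as.vector(sig_eff),
                       fixed = fixed, fixedval = fixedval, phi0 = phi,
                       tol = control$cg_tol, maxit = control$cg_maxit)
      phi <- sol$phi
      cg_total <- cg_total + sol$iterations
      E <- array(10 * .field_magnitude(phi, d, scene$spacing, as.vector(sig_eff)),
                 dim = d)
      conv <- TRUE
      break
    }
    delta <- delta_new
    if (iters >= control$picard_max) break
  }

  inset_a <- logical(n); inset_a[an_cells] <- TRUE
  inset_c <- logical(n); inset_c[ca_cells] <- TRUE
  sig_eff <- sig_t
  sig_eff[masks$active] <- control$sigma_metal
  sig_eff[masks$insulated] <- 0
  Ia <- .set_current(phi, d, scene$spacing, as.vector(sig_eff), inset_a)
  Ic <- .set_current(phi, d, scene$spacing, as.vector(sig_eff), inset_c)

  list(phi = array(phi, dim = d), E = E,
       current = (abs(Ia) + abs(Ic)) / 2,
       current_imbalance = abs(Ia + Ic),
       picard_iterations = iters, cg_iterations = cg_total,
       converged = conv, sigma = sig_t)
}

#' Solve a full pulse sequence and accumulate the field envelope
#'
#' Runs the drives of a [make_pulse_plan()] plan in order, carrying the
#' electroporation state between drives: each voxel's conductivity is
#' evaluated at the maximum field magnitude it has experienced so far. The
#' result is the field envelope -- the per-voxel maximum field over the
#' sequence -- which is the quantity compared against treatment target
#' fields.
#'
#' @inheritParams solve_drive
#' @param plan A [make_pulse_plan()] plan.
#' @return An object of class `field_envelope`: list with `E_max` (V/cm
#'   array), `sigma` (S/m final tissue conductivity state), `currents`
#'   (per-drive data.frame), `dims`, `spacing`.
#' @export
solve_sequence <- function(scene, plan, tissues = builtin_tissue_table(),
                           control = solver_control()) {
  stopifnot(inherits(plan, "pulse_plan") || is.data.frame(plan))
  d <- dim(scene$labels)
  scene$meta$solver_masks <- tissue_masks(scene)
  E_mem <- array(0, dim = d)
  cur <- vector("list", nrow(plan))
  prev_pair <- NULL
  phi <- NULL
  for (r in seq_len(nrow(plan))) {
    drive <- plan[r, ]
    pair <- sort(c(drive$anode, drive$cathode))
    phi0 <- if (identical(pair, prev_pair)) phi else NULL
    sol <- solve_drive(scene, drive, tissues, E_mem, control, phi0 = phi0)
    phi <- as.vector(sol$phi)
    prev_pair <- pair
    E_mem <- pmax(E_mem, sol$E)
    cur[[r]] <- data.frame(drive = r, anode = drive$anode,
                           cathode = drive$cathode, voltage = drive$voltage,
                           kind = drive$kind %||% NA_character_,
                           current_A = sol$current,
                           imbalance_A = sol$current_imbalance,
                           picard_iterations = sol$picard_iterations,
                           converged = sol$converged)
  }
  masks <- scene$meta$solver_masks
  structure(
    list(E_max = E_mem,
         sigma = sigma_from_field(scene, E_mem, tissues, masks),
         currents = do.call(rbind, cur),
         dims = d, spacing = scene$spacing),
    class = "field_envelope"
  )
}

#' @export
print.field_envelope <- function(x, ...) {
  cat(sprintf("<field_envelope %s voxels, peak %.0f V/cm, %d drives>\n",
              paste(x$dims, collapse = " x "), max(x$E_max),
              nrow(x$currents)))
  invisible(x)
}
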