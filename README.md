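# ectfield

Electric field modelling for electroporation-based liver tumor treatments
near hepatic blood vessels.

## What it is for

Electrochemotherapy (ECT) and irreversible electroporation (IRE) ablate
deep-seated liver tumors by delivering high-voltage pulses through needle
electrodes. A treatment succeeds only if the whole tumor experiences an
electric field above the treatment's target magnitude — 400 V/cm for ECT,
600 V/cm for IRE — so treatment plans are computed on patient-specific
numerical models. Blood conducts far better than liver, so hepatic vessels
next to a tumor act as field sinks; ignoring them, or segmenting them
inaccurately, can silently under-treat part of the tumor.

`ectfield` is a simulation pipeline for quantifying exactly that risk. It
is aimed at researchers in treatment-planning and tissue
bioelectromagnetics who want a scriptable, fully deterministic, tested
alternative to a commercial FEM workflow for these questions.

## The model

The package solves the nonlinear electro-quasistatic problem

∇·( σ(|∇φ|) ∇φ ) = 0

on a labeled voxel grid (liver, tumor, vessel wall, blood, electrodes),
with Dirichlet potentials ±V/2 on the driven electrode pair and no-flux
outer boundaries. Tissue conductivity σ rises from σ₀ to σ₁ as the local
field crosses the tissue's reversible (E₀) and irreversible (E₁)
electroporation thresholds, following a C1 smoothstep ramp; once a voxel
has been electroporated it keeps its elevated conductivity for the rest of
the pulse sequence. A treatment drives all neighboring outer electrode
pairs at one voltage and the diagonal (center-to-outer) pairs at another;
the per-voxel maximum field over the sequence — the field envelope — is
compared against the target field to give **tumor coverage** (% of tumor
volume at or above target; ≥ 99.9% counts as success), alongside the
collateral liver volume above 400 V/cm and the per-drive currents (50 A
generator limit).

Discretization is a structured finite-volume scheme with harmonic-mean
face conductivities, solved matrix-free by MIC(0)-preconditioned conjugate
gradients (Rcpp); the nonlinearity converges by damped Picard iteration.
Everything is deterministic.

On top of the solver sit: parametric scene generators (sphere tumor +
two-layer cylinder vessel; ellipsoidal patient-like stand-ins), electrode
placement per the clinical box/hexagon layouts, segmentation-error
perturbations (enlarge/shrink/shift of the vessel mask by 1 or 3 px),
electrode-collision resolution, a deterministic two-voltage optimizer, and
the study drivers `run_ignore_vessel_study()`,
`run_segmentation_error_study()` and `run_no_vessel_comparison()`.

## Worked example

Small ECT case: 10 mm tumor, 4 needles boxed around it 2 mm from the
tumor edge, driven at 600 V between neighbors and 1000 V across the
diagonals, with a 7 mm vessel touching the tumor:

```r
library(ectfield)

sc  <- build_simplified_scene(10, vessel_diameter = 7, distance = 0,
                              orientation = "parallel", spacing = 1)
el  <- place_electrodes(sc, "ECT", 4)
sc  <- rasterize_electrodes(sc, el)
plan <- make_pulse_plan(el, U_outer = 600, U_diag = 1000)
env  <- solve_sequence(sc, plan)
coverage(env, sc, "ECT")
#> <coverage_report ECT>  coverage 90.66% at 400 V/cm (insufficient), liver >=400 V/cm: 10144 mm^3
```

(The scene builder warns that the 0.7 mm vessel wall is rendered at one
1 mm voxel.) The same voltages cover the vessel-free tumor completely:

```r
sc0 <- build_simplified_scene(10, spacing = 1)
sc0 <- rasterize_electrodes(sc0, place_electrodes(sc0, "ECT", 4))
coverage(solve_sequence(sc0, make_pulse_plan(el, 600, 1000)), sc0, "ECT")
#> <coverage_report ECT>  coverage 100.00% at 400 V/cm (success), liver >=400 V/cm: 10680 mm^3
```

so a planner that ignored this vessel would predict success and deliver a
plan that leaves ~9% of the tumor under-treated — the central phenomenon
the package studies. (Numbers above are at 1 mm voxels; coverage is
mesh-stable to < 0.5 percentage points under halving.)

The segmentation-error workflow works the same way from
`build_patient_like_scene()`; see the methods vignette
(`vignettes/ectfield-methods.Rmd`) for the model details, parameter
defaults, verification against closed-form solutions, and known
deviations of the voxel solver from unstructured-FEM solutions of the
same configurations.

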