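Package: ectfield
Title: Electric Field Modelling for Electroporation-Based Liver Tumor Treatments Near Hepatic Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for treatment planning of electrochemotherapy
    (ECT) and irreversible electroporation (IRE) of liver tumors located near
    hepatic blood vessels. Builds parametric voxelized tissue models (spherical
    or ellipsoidal tumors, cylindrical vessels with wall and blood
    compartments, needle electrodes), solves the nonlinear electrostatic
    problem with electroporation-dependent tissue conductivity on a structured
    finite-volume grid, computes tumor coverage and healthy-tissue exposure
    metrics, optimizes electrode-pair voltages, and runs robustness studies
    quantifying how vessels -- and errors in their segmentation -- change the
    predicted electric field coverage of the tumor.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
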