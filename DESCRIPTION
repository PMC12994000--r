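Package: voxelenc
Title: Voxel-Wise Encoding Models with Layered-Network Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting voxel-wise encoding models that predict fMRI
    time series from the unit activations of layered action-value networks.
    Covers the full analysis path: stimulus-frame preprocessing and frame
    stacking, forward passes through feed-forward, dueling, and recurrent
    dueling architectures, construction of GLM design matrices (inactive-unit
    filtering, dual z-scoring, hemodynamic-response convolution, resampling to
    the acquisition grid, discrete-cosine high-pass filtering), L1-regularized
    voxel-wise regression with session-wise cross-validation and
    plateau-midpoint selection of the regularization strength, second-level
    inference (Fisher-Z, family-wise-error-corrected one-sample tests,
    repeated-measures ANOVA with Greenhouse-Geisser correction, normalized
    within-subject confidence intervals), and hierarchical layer-to-region
    mapping with compositional log-ratio statistics. A seeded synthetic-data
    generator produces a toy visuomotor stimulus stream, fixture network
    weights, region masks, and BOLD series with known sparse linear structure
    so that every stage is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    car,
    withr
Config/testthat/edition: 3
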