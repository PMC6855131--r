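Package: mmfuse
Title: Multimodal Brain-Map Classification, Redundancy and Fusion
Version: 0.1.0
Authors@R:
    person("FIDMAG", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cross-validated diagnostic classification of voxelwise brain
    maps from multiple MRI modalities, with train-only confound
    residualization (age, sex), four classifier families (ridge and lasso
    logistic regression, random forests, gradient boosting), a redundancy
    score quantifying shared predictive information between map types from
    test-set correctness indicators, and three multimodal integration
    strategies: probability-level fusion (mean, most-confident, logistic
    stacking), two-step sequential integration with per-modality voxel
    selection, and a one-dimensional convolutional network mixing
    modalities within voxel. Includes a synthetic multimodal cohort
    generator with controllable shared-signal structure, minimal NIfTI-1
    input/output, and a configuration-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    yaml,
    optparse,
    truncnorm,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
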