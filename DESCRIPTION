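Package: aidhs
Title: Automated and Interpretable Detection and Lateralization of
    Hippocampal Sclerosis from Surface-Based Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection and lateralization of hippocampal sclerosis (HS)
    from hippocampal surface-based morphometry, as produced by surface
    segmentation tools (per-vertex thickness, gyrification and curvature
    on a fixed-topology hippocampal surface, plus volumes and
    segmentation quality scores). Implements vertex outlier replacement,
    geodesic Gaussian smoothing and trimmed averaging to per-hemisphere
    features; empirical-Bayes multi-site harmonization preserving age,
    sex and disease-status covariates; left-referenced asymmetry indices
    normalized against healthy controls; normative growth charts
    (penalized-spline GAM centiles) with individual percentile scores; a
    three-class multinomial classifier (left HS / right HS / no HS) with
    balanced class weights, leave-one-site-out cross-validation and
    ensembling; per-feature abnormality thresholds; stratified
    performance evaluation; individualized HTML/JSON patient reports;
    and a seeded synthetic cohort generator emulating segmentation-tool
    outputs for end-to-end testing without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    mgcv,
    jsonlite,
    xml2,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    nnet,
    sva,
    withr,
    yaml
Config/testthat/edition: 3
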