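Package: adeeg
Title: Multichannel EEG Analysis for Staging Alzheimer's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multichannel EEG recordings of Alzheimer's
    disease patients across three clinician-defined states (calm,
    transitional, morbidity). Builds phase-locking-value (PLV) functional
    connectivity networks and computes weighted graph metrics (clustering,
    path length, global and local efficiency, betweenness); learns common
    spatial pattern (CSP) filters; converts single-channel series into
    thresholded and unthresholded recurrence-plot images; classifies those
    images with a small residual convolutional network; screens clinical
    covariates and fuses the EEG and clinical decision probabilities.
    Includes a seeded synthetic-EEG generator with controllable pairwise
    phase coupling and per-state amplitude regimes so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    nnet,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
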