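Package: neurocv
Title: Block-Aware Cross-Validation for Passive Brain-Computer Interface Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how the choice of cross-validation scheme biases
    accuracy estimates of passive brain-computer interface (pBCI) classifiers
    when the experimental block structure of EEG recordings is ignored.
    Provides a synthetic generator of block-structured multichannel EEG with
    independently controllable class effects and block-specific confounds,
    a harmonization preprocessing chain (zero-phase FIR notch/highpass,
    resampling, re-referencing, correlation-based bad-channel removal),
    Riemannian minimum-distance-to-mean classification of shrinkage
    covariance matrices (broadband and filter-bank block-diagonal variants),
    band-power and filter-bank CSP feature pipelines with mRMR selection and
    LDA, four cross-validation schemes (pseudo-online, leave-one-block-out,
    sequential and randomized stratified k-fold) with sample-size-corrected
    chance levels, and the statistical layer (bootstrap confidence intervals
    of scheme differences, Friedman and Durbin-Conover rank tests with
    Benjamini-Hochberg correction, Wilcoxon signed-rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
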