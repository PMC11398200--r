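Package: radrehab
Title: Therapeutic Exercise Recognition from Single UWB Radar Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end pipeline for recognizing upper-limb therapeutic
    exercises (left/bilateral shoulder abduction, shoulder flexion up/down,
    breaststroke) from impulse ultra-wideband radar scan matrices. Implements
    two-pulse-canceller clutter suppression, range-gated peak detection with
    fixed-length physiological windowing, 19 temporal and spectral descriptors
    per window, probability-level feature fusion of a small one-dimensional
    convolutional network with a random forest, and a stacked ridge-over-
    forest-and-boosting ensemble classifier, together with a synthetic
    radar-gram simulator that emulates the acquisition geometry, stratified
    splitting, weighted metrics, and five-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    ranger,
    rpart,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
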