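Package: swayscore
Title: Estimating Balance-Test Scores from Wearable Accelerometer Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for estimating m-CTSIB balance scores
    (center-of-pressure average velocity, inches per second) from body-worn
    tri-axial accelerometer recordings. Provides a calibrated synthetic
    postural-sway cohort generator, center-of-pressure posturography metrics
    (path length and average velocity), session segmentation and axis
    harmonization for eight standard sensor placements, a 42-feature
    time/frequency/entropy feature extractor, correlation-threshold feature
    selection, multiple linear regression, support vector regression and
    gradient-boosted tree models with grid-searched hyperparameters, and
    subject-wise leave-one-subject-out and grouped k-fold cross-validated
    evaluation (MAE, Pearson r, per-condition MAPE).
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
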