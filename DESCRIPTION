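Package: somnostage
Title: Sleep Staging from Tracheal Body Sound and Actigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Signal-processing and classification chain for a minimalistic
    type-4 ambulatory sleep monitor. Extracts respiratory features (breath
    detection from the 200-2000 Hz tracheal sound band after spectral
    subtraction), cardiac features (heart-beat detection from paired S1/S2
    peaks in the 5-30 Hz body-sound band, heart-rate-variability analysis)
    and movement features (quaternion orientation fusion of a 6-axis IMU,
    sleeping position and activity), classifies every 30-second epoch into
    2-, 3- or 4-stage sleep systems with a regularized linear discriminant,
    and evaluates hypnogram agreement (leave-one-out cross validation,
    per-stage accuracy, unweighted Cohen kappa), sleep-efficiency summaries
    and sleep-efficiency group screening with ROC analysis. Includes a
    synthetic-night generator producing stage-annotated audio, IMU and
    hypnogram data for end-to-end testing without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
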