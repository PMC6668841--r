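Package: vistl
Title: Visual Timelines of Inpatient Data for Deep-Learning Mortality Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts longitudinal inpatient observations from the first 48 hours
    of a hospital admission into normalized two-dimensional "visual timeline"
    images (variables by hours, pixel intensity equal to the normalized value) and
    predicts in-hospital mortality from them with a convolutional network carrying
    a recurrent layer (CNN-RL), alongside a standard convolutional and a recurrent
    baseline. Includes hourly blocking with last-observation-carried-forward,
    location-specific median imputation, min-max and direction-aware ("custom")
    normalization, correlation-based variable orderings, MEWS and SOFA early
    warning comparators, DeLong AUC comparison, Grad-CAM class-activation
    heatmaps, cohort differential images, and a seeded synthetic-cohort generator
    calibrated to published cohort marginals so the full pipeline is testable
    without access to real electronic health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pROC,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
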