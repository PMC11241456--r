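Package: noshowpricing
Title: Patient No-Show Prediction and Zero-Loss Dynamic Pricing for
    Appointment Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing patient attendance in hospital appointment
    systems and for deriving break-even penalty fees for non-profit clinics.
    Provides a seeded synthetic appointment-cohort generator with a logistic
    outcome model, ensemble classifiers (random forest, gradient boosting,
    AdaBoost) built on a compiled CART learner, a complete evaluation suite
    (confusion matrices, accuracy, weighted precision/recall/F1, Matthews
    correlation, ROC/AUC, calibration curves), a regression-based analysis
    of variance screen for attendance factors, and a revenue model that
    solves for the penalty surcharge on reappointed no-show patients under
    a zero-loss constraint, with a multi-day horizon simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
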