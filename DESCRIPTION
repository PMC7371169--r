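Package: ethocv
Title: Behaviour Classification from Collar Inertial Sensors with Honest
    Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates labelled multi-individual collar-mounted inertial
    sensor recordings (tri-axial acceleration, tri-axial angular rate and
    attitude at 50 Hz) for an eight-class canine ethogram, segments them
    into sliding windows, extracts time- and frequency-domain features,
    and classifies behaviours with a radial-basis-function support vector
    machine trained one-versus-one with calibrated class probabilities.
    Provides the two accuracy metrics used in animal behaviour
    recognition (overall accuracy and probability-threshold accuracy),
    random and per-individual (leave-one-subject-out) cross-validation,
    log-spaced hyperparameter grid search, confusion matrices with class
    merging, and experiment runners that quantify how random splitting of
    per-individual-correlated data overestimates accuracy and how
    optimizing threshold accuracy produces degenerate classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
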