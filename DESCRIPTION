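Package: ahpen
Title: Sparse Penalized Regression for the Additive Hazards Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variable selection and risk prediction for right-censored
    survival data under the semiparametric additive hazards model of Lin
    and Ying. Fits Lasso, SCAD and SICA penalized estimators of the
    least-squares-type loss by exact cyclic coordinate descent with
    warm-started regularization paths, tunes the penalty by K-fold
    cross-validation, and evaluates fitted risk scores with time-dependent
    ROC curves (cumulative/dynamic AUC under inverse probability of
    censoring weighting), Brier-type prediction error curves, the
    bootstrap .632+ prediction error estimator, and replicate stability
    tables for selected features. Includes a calibrated generator of
    high-dimensional gene-expression-like survival data for simulation
    studies, and an end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    survival,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
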