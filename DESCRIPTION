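Package: altscore
Title: Diagnostic Scoring Pipeline for Benign Versus Atypical Lipomatous
    Tumors on Multiparametric MRI Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to separate benign lipomas from atypical lipomatous
    tumors (ALT) using per-patient tables of MRI-derived features:
    contingency-table diagnostics (sensitivity, specificity, predictive
    values, odds and likelihood ratios, Fisher's exact test from the
    hypergeometric distribution), a two-group comparison procedure with
    normality-driven test selection, ROC construction with Youden-index
    dichotomization of continuous predictors, cross-validated gain-ratio
    feature ranking, a smoothed naive Bayes classifier with k-fold
    cross-validation, and an unweighted five-item ALT score (0-5 points,
    ALT called at 3 or more). A seeded Gaussian-copula generator produces
    synthetic two-group cohorts calibrated to published group summaries so
    the full pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    optparse
Config/testthat/edition: 3
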