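Package: mascard
Title: Diagnostic Models and a Weight-of-Evidence Scorecard for Macrophage
    Activation Syndrome Secondary to SLE
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates an early-identification pipeline for
    macrophage activation syndrome (MAS) secondary to systemic lupus
    erythematosus (SLE): a synthetic case-control cohort generator over the
    thirteen established clinical predictors, tiered missing-value imputation
    with a Mann-Whitney distribution-shift audit, clinically informed
    range-flag and composite features, two-stage feature selection
    (correlation and variance-inflation screening followed by cross-validated
    LASSO), four reference classifiers with grid search, leave-one-out
    validation and F-beta metrics, and a diagnostic scorecard built from
    chi-square (ChiMerge) binning and weight-of-evidence encoding with
    points-to-double-the-odds scaling, a Kolmogorov-Smirnov decision
    threshold, and kernel-density risk bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    glmnet,
    jsonlite,
    ranger,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
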