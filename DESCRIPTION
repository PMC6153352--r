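Package: pvsignal
Title: Propensity-Score-Based Signal Detection for Spontaneous-Report
    Pharmacovigilance Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal detection for spontaneous-report pharmacovigilance
    databases from individual reports rather than aggregated counts.
    Implements high-dimensional propensity-score (PS) strategies for each
    (drug, adverse event) pair -- PS estimation by BIC-lasso, the
    class-imbalance subsampling lasso (CISL), high-dimensional PS (hdPS)
    confounder ranking, or gradient tree boosting, combined with covariate
    adjustment, inverse-probability-of-treatment weighting (IPTW) or
    matching weights (MW) -- together with the univariate
    (disproportionality-style) and penalized multiple-regression
    comparators, one-sided testing with false-discovery-rate control, a
    synthetic spontaneous-reporting simulator with planted ground truth,
    and an evaluation harness scoring signal tables against reference sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    glmnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
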