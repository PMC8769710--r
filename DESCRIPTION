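Package: survfilter
Title: Filter Methods for Feature Selection in High-Dimensional Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature-selection toolkit for right-censored, high-dimensional
    survival data such as gene expression studies. Implements univariate
    filter scores (variance, correlation on martingale residuals, Cox score
    test, correlation-adjusted regression survival scores), feature-importance
    filters from random survival forests and Cox gradient boosting,
    mutual-information filters on categorized martingale residuals (mim,
    mrmr, jmi, jmim, disr, njmim, cmim), ridge-penalized Cox regression with
    internal cross-validated penalty selection, the integrated Brier score
    with inverse-probability-of-censoring weighting, the SMA-Count
    feature-selection stability measure, ordered-list ranking similarity,
    a nested cross-validation benchmark harness, and a seeded generator of
    gene-expression-like survival data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
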