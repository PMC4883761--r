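Package: postoprisk
Title: Predictive Analytics Pipeline for Postoperative Complication Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forecasts postoperative acute kidney injury and severe sepsis
    from preoperative electronic-health-record features. Implements the full
    predictive-analytics process: a synthetic cohort generator with known
    ground-truth risk functions, automatic outlier removal and imputation,
    outcome-conditional log-likelihood-ratio encoding of high-cardinality
    nominal features with rare-level grouping and k-means subgrouping,
    bottom-up prefix-tree aggregation of hierarchical surgical procedure
    codes, univariate/LASSO/PCA feature reduction, four risk models (logistic
    regression, generalized additive models with spline degree-of-freedom
    selection, naive Bayes, support vector machines), and a repeated
    stratified 70/30 evaluation harness with bootstrap confidence intervals
    and Hosmer-Lemeshow calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mgcv,
    glmnet,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
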