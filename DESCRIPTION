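Package: actidep
Title: Actigraphy Features and Interpretable Depression Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, testable pipeline for depression detection and
    severity classification from wrist-worn actigraphy. Reads per-minute
    activity recordings and a clinical scores table in the Depresjon CSV
    dialect, segments recordings into day windows, extracts time-domain,
    frequency-domain, circadian and transition features, balances classes
    with a from-scratch ADASYN implementation, trains and compares five
    classifiers under a repeated stratified cross-validation protocol with
    paired t tests and Holm correction, and explains the fitted models with
    exact coalitional Shapley values, a permutation-sampling approximation,
    and LIME-style local threshold-rule surrogates. A synthetic circadian
    cohort generator with planted group effects makes every stage testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    nnet,
    randomForest,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
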