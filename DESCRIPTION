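Package: radgrid
Title: Exhaustive Model-Combination Search for Radiomic Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated model selection for radiomics-style feature tables:
    exhaustively evaluates every combination of scaler, feature-selector
    chain, minority-oversampling scheme and binary classifier over repeated
    stratified train-test splits with inner K-fold cross-validation.
    Performance distributions (ROC AUC and accuracy) are aggregated into
    means with 95% percentile intervals, filtered by a well-performing
    threshold, summarised as selector-by-classifier heatmap matrices, and
    compared with the Mann-Whitney U test. All preprocessing, selection and
    resampling are fitted on training rows only, so the protocol is free of
    data leakage. Includes a seeded generator of radiomics-like synthetic
    tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    e1071,
    class,
    rpart,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
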