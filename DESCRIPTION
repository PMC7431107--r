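Package: radexplore
Title: Radiomics Feature Extraction and Exhaustive Model Exploration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless toolkit for radiomics model development. Extracts
    shape, first-order, and texture (gray level co-occurrence, run length,
    and size zone matrix) features from NIfTI image/ROI volumes; loads,
    audits, splits, and balances case-by-feature matrices; enumerates every
    combination of normalization, dimension reduction, feature selection,
    feature count, and classifier; evaluates each pipeline by stratified
    k-fold cross-validation; ranks models by validation AUC; applies the
    one-standard-error rule; and exports clinical statistics (AUC with
    bootstrap confidence intervals, accuracy, sensitivity, specificity)
    and machine-readable run manifests so any model can be re-inspected.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    MASS,
    e1071,
    rpart,
    randomForest,
    glmnet,
    nnet,
    kernlab,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
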