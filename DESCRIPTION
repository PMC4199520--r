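Package: faimsdx
Title: FAIMS Urinary Volatile-Organic-Compound Disease Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for discriminating disease classes from urinary
    volatile organic compound profiles measured by field asymmetric ion
    mobility spectrometry (FAIMS). Ion-current matrices over the dispersion
    field by compensation voltage plane are compressed with a 1-D Daubechies
    wavelet transform, filtered by coefficient variance, ranked by Wilcoxon
    rank-sum tests and classified (elastic-net sparse logistic regression,
    random forest, or support vector machine) under leave-one-out
    cross-validation with all feature selection nested strictly inside the
    training folds. Performance is reported as ROC curves, AUC with
    stratified-bootstrap confidence intervals, and sensitivity/specificity
    with exact Clopper-Pearson intervals. Includes a synthetic-cohort
    generator with planted, localized class signal for end-to-end validation,
    and a GC-MS chromatogram screen that detects peaks above an intensity
    threshold, bins them by retention time across samples and flags
    class-unique peaks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    randomForest,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
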