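Package: cpgclock
Title: Epigenetic Clocks, Relative-Age Transforms, and Methylation EWAS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction and unbiased evaluation of DNA-methylation age
    clocks from CpG beta-value matrices: sparse elastic-net age estimators
    with identity, log-linear, and relative-age (age / maximum lifespan)
    transforms for single- and dual-species clocks; leave-one-out and
    stratified k-fold cross-validation with Pearson R and median absolute
    error; epigenome-wide association screening for numeric traits and
    covariate-adjusted group contrasts with Stouffer meta-analysis and
    directional top-CpG selection; downstream intervention testing
    (DNAm age regressed on age, sex, and treatment), epigenetic age
    acceleration, and an out-of-bag random-forest sex predictor; plus a
    beta-distributed methylation-array simulator with a ground-truth table
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
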