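Package: ac4cpred
Title: Prediction of N4-Acetylcytidine (ac4C) Sites in mRNA with Gradient-Boosted Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies N4-acetylcytidine (ac4C) modification sites in mRNA from
    fixed-width candidate sequence windows. Implements formula-defined sequence
    feature encodings (one-hot, nucleotide chemical property, nucleotide density,
    k-mer composition, electron-ion interaction pseudopotential and its
    trinucleotide pseudo form), a gradient-boosted decision-tree classifier tuned
    for 1:9 class imbalance, stratified cross-validation with imbalance-aware
    metrics (accuracy, sensitivity, specificity, Matthews correlation, AUROC,
    AUPRC), baseline-classifier comparison, per-feature Shapley attribution and
    local surrogate explanations, and a seeded synthetic benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xgboost,
    Biostrings,
    jsonlite,
    stats,
    utils,
    e1071,
    randomForest,
    rpart
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
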