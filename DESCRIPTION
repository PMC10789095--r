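Package: psdosage
Title: Phase Separation and Gene Dosage Sensitivity Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links gene dosage sensitivity to liquid-liquid phase separation
    with two predictors and their evaluation machinery. TruncPS scores the
    phase-separation potential of protein regions lost to truncating variants
    using sequence-composition features (Kyte-Doolittle hydropathy, net charge
    per residue, Das-Pappu kappa charge patterning, SEG-style low-complexity
    proportion, disorder proportion) and a gradient-boosted tree ensemble.
    DosPS predicts phase-separating proteins from four dosage-sensitivity
    scores (pLI, LOEUF, pHaplo, pTriplo) with regularized logistic regression.
    The package also implements the four-rule classifier for premature
    termination codons escaping nonsense-mediated decay, ClinVar-style
    pathogenic-variant filters, rank-based AUC with repeated negative
    subsampling, stratified cross-validation, rolling-median confounder
    normalization, and seeded synthetic-data generators so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
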