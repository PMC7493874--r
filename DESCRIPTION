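Package: fpscreen
Title: Fingerprint-Based Virtual Screening with Convolutional Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based virtual screening workbench for binary bioactivity
    classification from molecular fingerprints. Computes seven 1024-bit
    fingerprint types, recodes them as signed {-1,+1} vectors, and classifies
    compounds with one- and two-dimensional convolutional neural networks, a
    majority-voting ensemble, and a stacked ensemble with a tuned MLP output
    head. Includes K-means derivation of the active/inactive IC50 threshold
    with elbow diagnostics, two train/test splitting schemes for precise
    discrimination and active-only early screening, SVM and random-forest
    reference models, a full evaluation suite (balanced accuracy, MCC, F1,
    AUC, log-loss) with enrichment-factor analysis, and a synthetic
    fingerprint generator so every stage can be exercised without external
    chemistry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    optparse,
    e1071,
    randomForest,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ChemmineR
Config/testthat/edition: 3
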