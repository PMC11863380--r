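Package: cabindr
Title: Calcium-Binding Site Prediction from Protein Language Model
    Embeddings with Multi-Window Convolutional Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-residue prediction of calcium-binding sites in ion-channel
    and transporter protein sequences. Couples per-residue protein
    language model embeddings (precomputed ProtT5/ESM-2/TAPE matrices or a
    seeded synthetic generator) with a multi-window convolutional scanner:
    parallel 1-D convolutions of several kernel sizes over the residue
    axis, global max-pooling, and a dense sigmoid classifier. Includes
    sequence-level train/test splitting, minority oversampling (random,
    SMOTE, ADASYN), PCA reduction and feature fusion of embedding sets,
    baseline classifiers, threshold-based confusion metrics
    (sensitivity, specificity, accuracy, Matthews correlation
    coefficient), exact rank-based ROC AUC, an ablation-grid runner, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    class,
    e1071,
    jsonlite,
    pROC,
    randomForest,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
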