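Package: colonyid
Title: Fungal Colony Identification from Chromogenic Profiles of Culture-Plate Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies fungal species from top-down photographs of culture
    plates by chromogenic profiling of colony colour patterns. Locates the
    Petri dish with a gradient-voting Hough circle transform over a blurred
    per-channel edge map, crops the best-fitting circular region, and
    classifies it with a convolutional neural network trained with
    augmentation, early stopping and checkpointing. Includes the full
    evaluation protocol (stratified 70/30 split, stratified 5-fold
    cross-validation, aggregate confusion matrices, per-species sensitivity,
    specificity, accuracy, PPV, NPV, F1 and Matthews correlation, and
    one-vs-rest ROC-AUC), a seeded synthetic plate-image generator for fully
    reproducible experiments, and a command-line interface with train, test,
    evaluate and simulate modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    optparse,
    rhdf5,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
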