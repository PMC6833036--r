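Package: stressecg
Title: Stress Detection from Raw ECG with a Dual-Branch 1-D Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end binary stress classification from raw, unfiltered
    electrocardiogram windows. Implements an eight-stage 1-D convolutional
    network in which each stage downsamples its input through two parallel
    branches (a strided convolution and a max-pooling layer) whose outputs are
    concatenated along channels, followed by batch normalization, rectified
    linear activation and dropout. Includes per-stressor z-score
    normalization, polyphase resampling to a common 256 Hz rate, fixed-width
    window slicing, three training regimes (from-scratch training on either
    corpus and transfer learning with all but the last stage frozen),
    subject-wise k-fold cross-validation, ROC/PR evaluation with conventional
    machine-learning baselines, and a seeded synthetic stress-modulated ECG
    simulator emulating a driving protocol and a mental-arithmetic protocol so
    the full pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    digest,
    FNN,
    glmnet,
    Rtsne
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
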