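Package: eegrecon
Title: Autoencoder Reconstruction Features for EEG Seizure Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects epileptic seizure states from single-channel EEG
    recordings by training a one-dimensional convolutional autoencoder on
    interictal signals only, quantifying how well each signal is
    reconstructed (mean squared error, original-to-reconstructed signal
    ratio in dB, and cosine similarity), and classifying the three-feature
    representation into healthy, interictal and ictal classes with random
    forest, AdaBoost and gradient-boosting ensembles. Includes a PCA
    feature baseline, permutation importance and exact Shapley values for
    model interpretability, a synthetic EEG generator for end-to-end
    testing without data downloads, and a reproducible pipeline driven by
    a configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    randomForest,
    rpart,
    xgboost,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
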