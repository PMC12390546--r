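Package: fnirsload
Title: Cognitive-Load Classification from fNIRS Time Series with a Compact CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and classification pipeline for working-memory load
    (n-back) decoding from multichannel functional near-infrared spectroscopy
    (fNIRS) recordings. Provides a synthetic-session generator with canonical
    double-gamma haemodynamic responses, load-graded prefrontal activation and
    physiological noise (cardiac, respiratory, Mayer-wave, drift); modified
    Beer-Lambert law conversion between optical density and chromophore
    concentration changes; per-channel standardization and overlapping or
    non-overlapping window segmentation; one-way ANOVA F-score channel ranking
    with Pearson correlation diagnostics; a from-scratch EEGNet-style
    depthwise-separable convolutional classifier with window-length-scaled
    hyperparameters, Xavier initialization, max-norm constrained spatial
    filters and Adam training; and a shared-fold k-fold cross-validation
    experiment grid over window length, segmentation mode and learning rate,
    reported as tidy tibbles with broom-style and ggplot2 methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
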