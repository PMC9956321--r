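Package: outlierboot
Title: Bootstrap Outlier Probabilities for Transcriptomics Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a per-sample outlier probability for transcriptomics
    data by running two-dimensional outlier detectors (a Tukey-depth bagplot
    and projection-pursuit robust PCA, 'PCA-Grid') inside a bootstrap
    resampling loop, with exact binomial inference (one-sided test against
    an outlier probability of 0.5 and one-sided Clopper-Pearson lower
    confidence bounds). Also provides the surrounding evaluation pipeline:
    simulation of expression data with planted outlier samples, log-CPM
    transformation and moderated-t feature ranking, and cross-validated
    classifier evaluation (SVM, random forest, LDA) under outlier-handling
    strategies that keep all samples, remove known outliers, or remove
    significant bootstrap outliers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    MASS,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    e1071,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
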