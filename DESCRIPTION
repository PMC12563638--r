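Package: msentropy
Title: Multi-Scale Fuzzy Entropy Features and Channel Selection for EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and evaluation toolkit for entropy-based
    classification of multi-channel EEG, built around fuzzy entropy and two
    multi-scale extensions: time-shifted multi-scale fuzzy entropy (interleaved
    subsequences per scale, no coarse-graining) and hierarchical multi-band
    fuzzy entropy (orthogonal wavelet band reconstruction with band-adaptive
    tolerance). Includes CSV/manifest signal I/O with standard EEG
    preprocessing (DC removal, zero-phase band-pass), trial epoching, fused
    per-trial feature matrices, six reference classifiers evaluated under
    leave-one-out, stratified 10-fold and leave-one-subject-out
    cross-validation, representative-channel selection with occurrence
    statistics, a synthetic two-condition EEG generator with a planted
    complexity contrast, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    signal,
    e1071,
    MASS,
    class,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
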