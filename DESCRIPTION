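Package: hvpeeg
Title: High Variability Period Metrics for Single-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments single-channel EEG into high and low amplitude-variability
    periods (HVPs/LVPs) by thresholding a moving-window amplitude standard
    deviation at a rank-based percentile, and summarises them as mean HVP/LVP
    duration, HVP area, HVP rate and duration ratio, with a baseline-anchored
    threshold rule for cross-condition comparison. Includes comparator metrics
    (sample entropy, Lempel-Ziv complexity, waveform complexity,
    harmonic-regression duration, relative band powers), a synthetic
    nonstationary EEG generator with programmable variance envelopes, paired
    and Tukey HSD condition comparisons, and a gradient-boosted-tree
    brain-state discrimination protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
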