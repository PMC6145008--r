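Package: hrvci
Title: Multiscale Entropy Complexity Indices for Heart Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies the complexity of heart rate variability from ECG or
    photoplethysmography recordings and uses it to separate levels of
    consciousness. Extracts interbeat-interval (tachogram) series with an
    FFT bandpass filter and a derivative-energy QRS/pulse detector, screens
    ectopic beats, computes coarse-grained multiscale sample entropy
    (m = 2, r = 0.15) over scales 1-10 and the short- and long-scale
    Complexity Indices, compares groups with an exact Mann-Whitney test and
    Spearman rank correlation, and induces a One-R single-attribute
    diagnostic rule with stratified k-fold cross-validation and a full
    confusion-matrix metric panel. A seeded synthetic cohort generator
    (oscillation + 1/f + white-noise interbeat mixtures with CRS-R-like
    behavioural scores) exercises the whole pipeline without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
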