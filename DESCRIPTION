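Package: mplzc
Title: Multiscale Permutation Lempel-Ziv Complexity for Biomedical Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complexity analysis of univariate biomedical time series by
    Lempel-Ziv exhaustive-history parsing over symbol streams. Implements
    classical binary Lempel-Ziv complexity (mean/median thresholding),
    permutation Lempel-Ziv complexity built on ordinal-pattern (Bandt-Pompe)
    symbolization, and its multiscale extension over coarse-grained series,
    together with seeded generators for a battery of synthetic benchmark
    signals (noise, chirps, band-limited noise, autoregressive and MIX
    processes), sliding-window profiling, and a focal vs non-focal EEG
    group-analysis and classification pipeline (Mann-Whitney statistics and
    cross-validated support-vector classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
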