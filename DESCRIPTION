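Package: nvcoupling
Title: Neurovascular Coupling Analysis of Joint NIRS-EEG Recordings Under
    tDCS Block Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate neurovascular coupling from synchronized
    cerebral oximetry (rSO2, 10 Hz) and EEG (500 Hz) recorded under a
    randomized ON/OFF transcranial direct current stimulation block design.
    Implements Empirical Mode Decomposition by cubic-spline envelope sifting,
    peak-power screening of intrinsic mode functions, log10 mean-power
    transformation of EEG modes, lagged normalized cross-correlation with a
    white-noise significance bound and zeroing rule, and block-design
    aggregation into trial-by-lag coupling maps with onset detection. A
    synthetic session generator with planted lag, onset and artifacts makes
    the whole pipeline verifiable by parameter recovery. Includes a slim
    spherical-geometry helper for NIRS optode placement along scalp arcs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
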