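Package: plicrit
Title: Phase-Lock Intervals, Power-Law Criticality Statistics and Adaptive
    SOC Network Models for Multichannel Neural Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test multichannel electrophysiological recordings for
    signatures of critical brain dynamics. Extracts phase-lock intervals (PLI)
    between channel pairs from an analytic (Hilbert-pair) dyadic wavelet
    decomposition, fits power laws to PLI duration distributions by
    maximum likelihood with Kolmogorov-Smirnov selection of the lower cutoff,
    bootstrap goodness-of-fit and likelihood-ratio model comparison, and tracks
    a signed deviation statistic against a frozen reference fit over sliding
    windows. Includes an adaptive self-organized-criticality threshold-network
    simulator (Bornholdt-type activity-dependent rewiring) with a compiled
    synchronous-update kernel, and a surrogate-recording generator with
    controllable baseline/seizure/recovery phase-locking regimes so the full
    pipeline can be exercised end to end without clinical data.
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
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
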