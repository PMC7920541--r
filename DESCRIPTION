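Package: oscnet
Title: Oscillatory Network Mapping from Multisite Local Field Potentials
Version: 0.1.0
Authors@R: person("Ramos", "Delgado", email = "oscnet@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multisite local field potential (LFP)
    recordings collected during a self-paced go/wait (action postponement)
    task. Provides a synthetic session generator with planted oscillatory
    bursts and phase-coupled channel pairs, epoching with amplitude-based
    artifact rejection and median referencing, Morlet wavelet time-frequency
    decomposition with baseline normalization and session z-scoring,
    whole-matrix FDR-corrected one-sample and dual-masked contrast
    statistics, weighted phase-lag index (wPLI) connectivity with baseline
    correction and network graph thresholding, and decoding of impulsive
    versus patient trial outcomes from theta-band power and connectivity
    using logistic regression and a time-resolved linear support-vector
    machine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
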