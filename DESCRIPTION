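Package: cgsync
Title: Burst Synchrony and Electrical Coupling Analysis for Cardiac
    Ganglion Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired intracellular recordings from
    crustacean cardiac ganglion motor neurons: spike detection and
    amplitude-based unit classification on extracellular traces, burst and
    cycle segmentation (including double-burst boundary rules), per-burst
    waveform synchrony as the squared zero-lag Pearson correlation, phase and
    burst statistics with consecutive-cycle averaging, and electrical-coupling
    estimation (coupling coefficients, input/transfer resistances, and the
    Bennett two-compartment coupling conductance). A synthetic-data generator
    produces passive cell pairs with exactly known coupling and small
    heterogeneous bursting networks with gap junctions and phenomenological
    neuromodulator transforms, so the whole pipeline is testable against
    ground truth without any recording download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
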