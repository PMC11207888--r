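Package: fatiguePLI
Title: Phase Lag Index Brain Networks for Driving-Fatigue EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Band-wise Phase Lag Index (PLI) functional connectivity analysis
    of sustained-driving EEG sessions. Builds per-subject, per-band,
    per-epoch PLI networks from the Hilbert-transform instantaneous phase,
    fits an ordinary-least-squares trend to every connection across the
    session, gates connections by explained variance and significance,
    and aggregates individual networks (IN) into prevalence, shared-edge,
    global-network (GN) and IN/GN overlap summaries. Includes a
    deterministic synthetic EEG generator with planted, phase-lagged,
    linearly drifting couplings for end-to-end validation, plus EDF input
    and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
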