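Package: mechwtd
Title: Waiting-Time Distributions of Critical Events in Osteoblast
    Mechanotransduction Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Stochastic agent-based simulation of the integrin-RAF-MEK-ERK-RUNX2
    mechanotransduction network of a single osteoblast under square-wave
    mechanical loading, together with a subordination-inversion pipeline that
    extracts critical events from noisy molecular count time series and
    estimates amplitude-weighted waiting-time distributions (WTDs) of
    recurring events. Includes a forward generator of subordinated processes
    with planted ground truth for validating the inversion, moving-average
    de-trending, Hilbert-envelope rectification, prominence-based event
    detection, weighted kernel density estimation of signal interim periods,
    epoch-resolved (ageing) WTDs and replicate confidence bands.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
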