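Package: bnet
Title: Bi-Path Residual Networks for Nanopore Resistive-Pulse Signals
Version: 0.1.0
Authors@R:
    person("Signal", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Physics-based simulation of solid-state nanopore current traces
    (open-pore current from a resistance model, steric-blockade pulses,
    four-component colored background noise, baseline jumps and drift) with
    fully labeled ground truth, a classic prominence-threshold event
    detector, and a bi-path one-dimensional residual network (B-Net) that
    regresses per-window pulse count, mean amplitude, and mean dwell time.
    Includes the training, gated-inference and error-aggregation protocol
    needed to compare learned and threshold-based feature extraction on
    identical synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
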