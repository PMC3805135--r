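Package: pyloop
Title: Closed-Loop Dopaminergic Regulation of the IA:Ih Conductance Ratio in a
    Rhythmic Motor Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how a neuromodulator can stabilise a central
    pattern generator by closing a feedback loop between circuit activity and
    an ionic conductance. The package generates synthetic pyloric-like paired
    pacemaker/follower spike trains and voltage-clamp current traces, computes
    burst and phase metrics (cycle period, LP-on delay and phase, burst
    duration, interspike intervals) with 10-cycle averaging, implements the
    two-electrode voltage-clamp measurement chain (single-exponential
    back-extrapolation, prepulse leak subtraction, conductance conversion,
    first-order Boltzmann activation fits), provides Hodgkin-Huxley-style
    conductance models of the hyperpolarization-activated current (Ih) and the
    transient A-type potassium current (IA) with forward-Euler integration and
    an offline dynamic-clamp stream, encodes a dopamine-enabled
    activity-dependent rule relating burst duration, cycle frequency and spike
    activity to the Ih maximal conductance, and composes these into closed-loop
    clamp-protocol emulations and a minimal post-inhibitory-rebound network
    simulation demonstrating firing-phase advance and recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
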