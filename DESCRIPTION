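Package: adexz
Title: Extended Adaptive Exponential Integrate-and-Fire Neurons with Slow
    Ionic Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and slow-fast analysis of an adaptive exponential
    integrate-and-fire (AdEx) neuron extended with a slow impairment variable z
    that aggregates deficits of ionic regulation, pushing the cell from
    quiescence through tonic spiking and pathological bursting to sustained
    ictal firing. Provides fixed-step integrators for the single neuron and for
    conductance-based networks of regular-spiking and fast-spiking cells with an
    impaired excitatory subpopulation, fixed-point and bifurcation analysis of
    the frozen-z fast subsystem (Andronov-Hopf and saddle-node detection),
    interspike-interval based classification of firing patterns, regime-boundary
    sweeps, and (Z0 x N_SC) parameter-plane exploration with region labelling of
    seizure-like propagation.
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
    optparse
Config/testthat/edition: 3
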