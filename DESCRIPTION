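Package: tesync
Title: Transient Explosive Synchronization in Resource-Constrained
    Adaptive Kuramoto Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of transient explosive
    synchronization (tES) in Kuramoto oscillator networks with
    synchrony-driven adaptive coupling and a per-node excitability
    resource. Provides generators for small-world, scale-free, random
    and brain-like modular networks, a fast Euler integrator for the
    coupled phase/resource dynamics, adiabatic hysteresis and
    bifurcation sweeps with tipping-point detection, seizure-like
    transient extraction, intra- and intermodular synchrony statistics,
    a synchronization cluster tracking algorithm (SCTA) with
    driver-node identification, and recovery-to-consumption ratio
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
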