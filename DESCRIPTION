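Package: ctbgsim
Title: Corticothalamic-Basal Ganglia Neural Field Simulation of Deep Brain
    Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a nine-population neural field model of the
    corticothalamic-basal ganglia system with population-level deep brain
    stimulation (DBS) of the subthalamic nucleus. Provides steady-state
    solving and linearized gain analysis, a fixed-step fourth-order
    Runge-Kutta integrator for the spatially uniform delay differential
    system, DBS pulse-train stimuli with amplitude calibration, Welch
    power-spectrum estimation, and experiment presets for parkinsonian
    beta-rhythm generation, suppression by high-frequency stimulation,
    and entrainment scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
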