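Package: quorumsync
Title: Robust Synchronization Analysis of Stochastic Coupled Genetic Oscillators
Version: 0.1.0
Authors@R:
    person("quorumsync", "developers", email = "quorumsync@example.org",
           role = c("aut", "cre"))
Description: Simulation and robust-control analysis of a population of
    stochastic repressilator circuits coupled by a quorum-sensing
    autoinducer. Provides Ito stochastic differential equation simulation
    of the coupled network under intrinsic kinetic-parameter fluctuations
    and extrinsic molecular noise, Monte-Carlo estimation of the H-infinity
    noise-filtering energy ratio, Takagi-Sugeno fuzzy interpolation of the
    synchronization-error dynamics from analytic Jacobians, and a linear
    matrix inequality (LMI) machinery for certifying robust synchronization:
    feasibility with independent eigenvalue verification, bisection for the
    optimal filtering level, design of an external quorum-sensing control
    gain, robustness decomposition, and Hamilton-Jacobi inequality residual
    audits for quadratic storage functions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
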