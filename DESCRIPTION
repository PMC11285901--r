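Package: abetadyn
Title: Bistability and Hysteresis in an Amyloid-Beta/Neuroinflammation Kinetic Model
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and qualitative analysis of a five-species kinetic model
    of Alzheimer's disease progression coupling amyloid-beta monomers, free
    oligomers, plaque-bound oligomers, microglial cells and interleukins.
    Provides the reaction right-hand side and an adaptive Runge-Kutta
    integrator (compiled), enumeration of all non-negative steady states via a
    scalar reduction of the stationary system, linear stability through the
    analytic Jacobian, saddle-node bifurcation tracing in the monomer
    degradation rate, and basin-of-attraction threshold maps over initial
    inflammation and initial monomer load located by bisection. Ships the
    published parameter and initial-condition presets and a small command-line
    interface for reproducible CSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
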