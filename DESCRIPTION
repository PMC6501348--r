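Package: dimerbath
Title: Multi-Resolution Simulation of a Bead-Spring Dimer in Heat Baths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a bead-spring dimer coupled to two kinds of explicit
    heat baths and to their macroscopic Langevin limit. The short-range bath
    is a gas of point particles exchanging momentum with the monomers through
    elastic collisions, simulated inside a co-moving cubic frame with
    stochastic boundary insertion of incoming solvent (acceptance-rejection
    sampling of erfc-tail depth distributions and truncated-Gaussian
    velocities). The long-range bath is a Kac-Zwanzig ensemble of harmonic
    oscillators with exponentially distributed frequencies whose friction
    kernel is Lorentzian. Mixed-resolution integrators evolve one monomer by
    molecular dynamics while the other follows Langevin dynamics. Estimators
    for the mean dimer length, the centre-of-mass velocity autocorrelation
    function and Green-Kubo diffusion constants allow validation against the
    closed-form Langevin statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
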