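Package: substratewaves
Title: Travelling Waves in Substrate-Mediated Tissue Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and travelling-wave analysis for a minimal continuum
    model of cell invasion in which the diffusive flux of cells is
    proportional to a substrate that the cells deposit and which decays in
    time. Provides implicit finite-difference solvers for the coupled
    cell/substrate system in one and two dimensions, front tracking and
    long-time wave-speed estimation, parameter sweeps for the minimum wave
    speed and the dispersion relation, the desingularised travelling-wave
    phase space with its slow-manifold reduction and a geometric
    sharp/smooth front classifier, and closed-form and large-speed
    perturbation reference solutions including the Porous-Fisher limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
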