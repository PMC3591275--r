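Package: epimotion
Title: Stochastic Interacting-Particle Simulation of Collective Epithelial Cell Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the collective motion of cells in an expanding epithelial
    monolayer as a system of stochastically moving, interacting point particles:
    Langevin velocity dynamics with Ornstein-Uhlenbeck colored noise, velocity
    alignment between sector-defined nearest neighbors, and short-range central
    forces. Includes a band geometry with a damageable free surface, leader
    cells that drive finger formation at the border, density-capped cell
    division, the velocity-field statistics used to compare particle models to
    PIV-style data (histograms, pair correlation, spatial and temporal velocity
    correlation, border kinetics, velocity profiles, finger density), a
    correlation-function parameter-fitting loop (Nelder-Mead on a curve
    mismatch with noise-amplitude calibration), and the analytically solvable
    frozen-position triangular-lattice approximation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
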