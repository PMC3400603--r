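Package: stigmergy
Title: Individual Trail-Following Rules and Collective Pheromone Trail Dynamics in Ants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing how individual ants respond to trail
    pheromone and how those responses scale up to collective trail
    formation and binary path choice. Reconstructs a passage-count
    pheromone field from time-stamped trajectories, extracts short
    two-segment tracking events with turning angles, and fits a
    Weber's-law turning response (turning angle proportional to the
    left/right pheromone contrast) with per-band slopes, a power-law
    slope-concentration relation, a detection threshold, and a
    pixel-pair correlation map. Includes an off-lattice agent-based
    simulator of trail formation in an open arena and of choice on a
    symmetric binary bridge, a drift-diffusion (error-function) model of
    branch choice, and the two-branch flux model whose stationary states
    display a pitchfork bifurcation. A seeded synthetic-data generator
    with ground-truth logs supports parameter-recovery and null tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
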