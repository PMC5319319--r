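Package: confusim
Title: Virtual Predation on Simulated 3D Starling Flocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of the confusion effect in three
    dimensions. Provides a StarDisplay-style starling flock model with
    topological (7-nearest-neighbour) coordination and calibrated density,
    a steerable predator with roll/pitch/thrust flight dynamics, a scripted
    pursuit controller whose target belief swaps stochastically among nearby
    distractors, a trial engine reproducing the virtual-predation protocol
    (100 m start distance, 50 m altitude, fading target trail, 30 s
    timeout), factorial experiment scheduling, trajectory kinematics
    (speed, tangential acceleration, curvature), and the mixed-model
    likelihood-ratio analysis of targeting error and hunting time as
    functions of flock size and density.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
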