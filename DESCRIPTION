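Package: raftsim
Title: Agent-Based Lattice Simulation of Lipid Raft Formation in Brain
    Cell Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grain agent-based (cellular automata) simulation of
    lipid microdomain formation in a cell membrane monolayer. Lipid
    classes are represented as cylinders interacting through non-retarded
    additive London-Van der Waals attraction; stochastic neighbor
    exchanges on a 200x200 periodic lattice produce low-mobility regions
    identified with lipid rafts. Includes raft size/number estimators,
    peroxidability-index mapping, a random-composition validation
    statistic with confidence intervals, and bundled human frontal-cortex
    lipid composition tables for Control and three Alzheimer's disease
    Braak-stage scenarios so all four conditions run end-to-end with no
    external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
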