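Package: cma2d
Title: Cooperative Motion Monte Carlo for Two-Dimensional Polymer-Solvent Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lattice Monte Carlo simulation of athermal two-dimensional
    polymer solutions with explicit solvent on a fully occupied triangular
    lattice, using the cooperative motion algorithm (CMA): molecular
    elements move collectively along closed displacement loops so that no
    vacancies are ever created.  Provides the conformational observable
    suite (radius of gyration, end-to-end distance, gyration-tensor
    eigenvalues and asphericity, intramolecular correlation function,
    single-chain static structure factor, center-of-mass pair correlation,
    solvent domain statistics), power-law scaling analyses for the Flory
    exponent and blob-crossover detection in the structure factor, and
    deterministic reference fixtures (rods, disks, exhaustive self-avoiding
    walk enumeration, ideal random walks) that serve as exact oracles for
    every observable.  Supports single-layer (strictly 2D) and two-layer
    (quasi-2D) periodic boxes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
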