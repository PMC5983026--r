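Package: thermoring
Title: Interface Energetics, ATPase Kinetics and Allosteric Cycling of
    Double-Ring Chaperonin Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hetero-oligomeric double-ring chaperonin
    (thermosome) assemblies: typed ring topologies with intraring, facing and
    diagonal neighbour relations; multi-model PDB snapshot trajectories;
    rigid-body (Kabsch) superposition and homo-oligomer construction;
    idealized point mutation of side chains; an empirical pairwise interface
    potential (soft-core Lennard-Jones plus distance-dependent-dielectric
    Coulomb) with per-subunit global/separated/diagonal interface-energy
    decomposition; steady-state ATPase kinetics with one- and two-classes-of-
    sites Michaelis-Menten fitting, blank correction and refolding yields; and
    a stochastic simulator with an exact Markov-chain oracle for the
    neighbour-gated ATPase cycle of alternating-subunit rings. Synthetic-data
    generators produce toy assemblies, jittered trajectories and rate curves
    for testing and method exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
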