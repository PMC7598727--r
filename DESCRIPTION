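Package: fibriltwist
Title: Cluster Detection, Shape Descriptors and Helicity Order Parameters
    for Coarse-Grained Peptide Aggregation Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for coarse-grained peptide aggregation
    trajectories. Detects aggregates by a single-linkage bead-distance
    criterion under periodic boundary conditions (with merging of clusters
    split across boundaries), computes shape and order descriptors
    (radius of gyration, gyration-tensor asphericity, end-to-end
    orientation correlation, beta-content, mass-center distance
    histograms), and quantifies fibril twist through a ribbon-based
    cluster helicity order parameter. Includes kinetic-curve reductions
    (half-times, cluster-peak times, scaled master curves), power-law
    scaling fits of cluster growth, box/concentration utilities, a
    seeded synthetic-structure generator (helical fibrils, sheet stacks,
    amorphous clusters, monomer gases) with analytically known descriptor
    values, and a Gillespie simulator of stochastic coalescence kinetics.
    Readers and writers for XYZ, PDB and GRO coordinate files bind frames
    to a bead-level peptide topology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    bio3d,
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
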