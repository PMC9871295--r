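Package: bmbsr
Title: Back-Mapping Based Sampling Analysis for Multi-Domain Protein
    Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis workbench for comparing coarse-grained and atomistic
    conformational ensembles of multi-domain proteins such as polyubiquitin
    chains. Computes residue-wise minimal-distance collective variables,
    trains an autoencoder with a sketch-map distance-matching loss to obtain
    a two-dimensional conformational map, selects simulation seeds from that
    map by minima-focused, Boltzmann-weighted or uniform strategies, monitors
    ensemble convergence with a unity-normalised earth mover's distance
    (exact optimal transport between 2D histograms), and assigns
    conformations to states with an iterative density-based clustering
    workflow (correlation embedding + HDBSCAN + RMSD-gated expansion).
    Includes a synthetic three-domain ensemble generator with planted
    metastable states for validation and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
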