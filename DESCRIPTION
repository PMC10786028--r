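Package: nehdx
Title: Nonequilibrium Hydrogen/Deuterium-Exchange Mass Spectrometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for nonequilibrium hydrogen/deuterium-exchange
    mass spectrometry (neHDX-MS) of ligand-induced conformational transitions.
    Reads peptide-level centroided deuterium-uptake tables for apo, equilibrium
    end-point and nonequilibrium states, normalizes uptake by the maximum
    exchangeable amide count, averages overlapping peptides to residue
    resolution, fits stretched-exponential exchange kinetics, computes
    per-residue two-dimensional sum-difference coordinates, classifies the nine
    archetypes of transient (de)protection, clusters residues with correlated
    kinetics (k-means plus a centroid dendrogram), checks ligand-site
    saturation within the labeling dead time, and analyzes multi-model
    structural interpolation trajectories (backbone hydrogen-bond breaking
    events, pairwise Kabsch RMSD matrices, per-residue label painting).
    Includes a mechanistic forward simulator of EX2 exchange during a
    three-state conformational relaxation that provides ground truth for every
    downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    cluster,
    ape,
    bio3d,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    deSolve
Config/testthat/edition: 3
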