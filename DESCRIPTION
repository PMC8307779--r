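Package: enscape
Title: Conformational Ensemble Analysis and Free-Energy Landscapes for
    Disordered Protein Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of conformational ensembles of intrinsically
    disordered polypeptides sampled by molecular dynamics: multi-model PDB
    ensemble handling with Kabsch superposition, per-frame and per-residue
    structural descriptors (RMSD, RMSF, radius of gyration, solvent
    accessible surface area), secondary-structure assignment from backbone
    hydrogen-bond energies with helix segment statistics, dynamic contact
    maps and non-covalent interaction networks, ensemble-based RMSD
    clustering, relative free-energy landscapes over reaction-coordinate
    pairs by k-nearest-neighbour density estimation with well detection,
    and per-residue finite-state Markov models of folding dynamics
    compared across replicas by Fisher-Rao distances and classical
    multidimensional scaling. Includes generators for synthetic ensembles
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
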