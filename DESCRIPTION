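Package: mqsar
Title: Molecular Quantum Similarity, Rigid Superposition, Reactivity
    Descriptors and Field-Based QSAR for Ligand Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of congeneric ligand series
    against a protein binding pocket. Implements molecular quantum
    similarity measures (overlap and Coulomb operators) over promolecular
    Gaussian densities with Carbo and distance indices, a topo-geometrical
    rigid superposition algorithm based on bonded-pair and triad matching,
    conceptual-DFT global reactivity descriptors (chemical potential,
    hardness, softness, electrophilicity) and condensed Fukui functions,
    per-residue interaction-energy decomposition with critical-residue
    ranking, and a CoMFA-style 3D-QSAR stage (steric/electrostatic grid
    fields, partial least squares, leave-one-out cross-validation,
    contribution contours). A synthetic-data module generates macrocycle-like
    ligand series, pseudo-residue pockets with an additive energy model, and
    descriptor tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    bio3d
Suggests:
    ChemmineR,
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
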