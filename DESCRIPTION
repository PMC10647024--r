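Package: confstrain
Title: Strain Energy of Bound Ligand Conformations in Conformer Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies where receptor-bound (bioactive) small-molecule
    conformations sit in the potential-energy distribution of their
    conformer ensembles. Provides a conjugate-gradient geometry optimizer
    with backtracking line search and Gaussian-style convergence criteria
    over pluggable potential-energy surfaces (analytic test surfaces, a
    force-field adapter, and an ensemble-of-models adapter with a committee
    uncertainty statistic), molecule-identity verification by element-path
    matching, optimal-superposition (Kabsch) RMSD, conformer-ensemble
    energy bookkeeping with bound-conformation scenario classification,
    strain-energy (delta-E) distribution and pruning-threshold statistics,
    per-molecule benchmark metrics, and a seeded synthetic-data generator
    so the entire pipeline is testable without external structure
    downloads or model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
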