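Package: mdhinge
Title: Comparative Trajectory Analysis of Multi-Domain Hinge Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of molecular dynamics
    trajectories of multi-domain proteins that open and close about a
    hinge. Provides multi-model PDB trajectory input and output, Kabsch
    least-squares superposition, whole-protein and per-domain RMSD,
    per-residue RMSF, radius of gyration, inter-domain centre-of-mass
    distances and hinge angles, a delta-RMSD open/closed progress
    variable with state classification, persistence-filtered protein
    structure networks (salt bridges, hydrogen bonds, hydrophobic
    contacts) with hub and delta-degree analysis, a coarse-grained
    synthetic hinge-trajectory generator with known ground truth, and a
    multi-system analysis pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
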