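Package: phnmr
Title: Comparative Structural NMR Analysis of Pleckstrin Homology Domains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative solution-NMR structural analysis of
    pleckstrin homology (PH) domains and their peptide ligands: multi-model
    PDB ensemble input/output, Kabsch least-squares superposition with
    region-restricted RMSD and ensemble coordinate precision, pairwise
    global sequence alignment and region-restricted percent identity, NOE
    distance-restraint binning and sequence-separation classification,
    HSQC titration peak tracking with combined chemical-shift-perturbation
    mapping, steady-state heteronuclear NOE mobility analysis, and
    single-site isothermal titration calorimetry simulation and fitting.
    Seeded synthetic-data generators emulate every input class with known
    ground truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StructuralBioinformatics, Proteomics, Software
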