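Package: cgmdr
Title: Residue-Level Coarse-Grained Molecular Dynamics of Proteins and
    Nucleic Acids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and simulates residue-level coarse-grained (CG) models of
    proteins, DNA and RNA.  Proteins are reduced to one bead per residue at
    the C-alpha position; nucleotides to three beads (phosphate, sugar,
    base).  The package maps atomistic structures (PDB or PDBx/mmCIF) to CG
    particles, detects Go-type native contacts, builds sequence-dependent
    double-stranded DNA from sequence alone, and writes GROMACS-dialect
    topology and coordinate files.  A compiled engine evaluates
    structure-based (AICG2+-style, Go/12-10), hydropathy-scale (HPS/KH,
    Ashbaugh-Hatch), three-site-per-nucleotide DNA (base stacking, Watson-
    Crick pairing, cross stacking), position-weight-matrix protein-DNA
    recognition and screened Debye-Hueckel electrostatic terms with per-term
    cell-linked-list neighbor lists, and integrates Langevin dynamics with a
    velocity-Verlet scheme and deterministic counter-based noise.  Analysis
    helpers compute the radius of gyration, superposed RMSD, fraction of
    native contacts, slab density profiles, radial distributions, and
    DNA-specific observables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
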