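Package: IDPAnchor
Title: Anchor-Residue and Side-Chain Rotamer Analysis for Disordered
    Peptide Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies anchor residues in peptide-protein complexes from
    solvent-accessible surface area (SASA) burial and quantifies how often
    unbound conformational ensembles of an intrinsically disordered peptide
    sample bound-like side-chain rotamer states. Implements a deterministic
    Shrake-Rupley SASA engine, chi1/chi2 dihedral extraction with circular
    rotamer-region classification, joint two-residue state analysis,
    transition counting with debouncing, simplified helix assignment with
    helix-unfolding-time detection, and an ideal-geometry synthetic ensemble
    generator with known ground truth. The worked examples follow the p53
    transactivation peptide (Glu17-Asn29) and its MDM2 and Taz2 binding
    modes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
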