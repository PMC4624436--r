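Package: altconf
Title: Multiconformer Protein Model Building in Real-Space Electron Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatically detects and models alternative protein backbone and
    sidechain conformations, including peptide flips and glycine shifts, in
    real-space electron-density maps. Candidate conformations are generated by
    ellipsoid-guided backbone displacement with nullspace inverse-kinematics
    chain closure, stereotyped peptide-flip transforms, and rotamer-library
    sidechain sampling; per-residue occupancies are selected by a quadratic
    program followed by an exact threshold- and cardinality-constrained
    mixed-integer quadratic program. Includes peptide-flip geometry mining and
    clustering, tight-turn and glycine-enrichment statistics, synthetic
    electron-density dataset generation, and a fragment-scale true/false
    positive benchmark. Reads and writes multiconformer PDB coordinates
    (altloc, occupancy, ANISOU) and CCP4/MRC maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    quadprog
Config/testthat/edition: 3
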