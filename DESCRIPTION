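Package: csgkit
Title: Force-Field Parameterization and Structural Validation of
    S-Glutathionylated Cysteines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building force-field-ready S-glutathionylated
    cysteine (CSG) residues and validating them against experimental
    structures. Implements two-stage restrained electrostatic potential
    (RESP) charge fitting from electrostatic-potential grids, the
    cap-zeroing/backbone-freezing charge-normalization scheme used for
    modified amino acids, AMBER OFF residue-library and TRIPOS mol2
    output, missing-parameter checking against frcmod-style tables, in
    silico grafting of glutathione onto target cysteines by
    internal-coordinate construction, and a descriptor suite for
    structural ensembles (Kabsch superposition and RMSD series, radius
    of gyration, S-S dihedrals, native-interaction distance monitoring,
    and average-linkage conformational clustering). Deterministic
    synthetic-fixture generators (toy peptides, point-charge ESP grids,
    seeded perturbation trajectories) make the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
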