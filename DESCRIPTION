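Package: semiflex
Title: Rigid-Body Ensemble Modeling from Distance-Distribution Restraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative ensemble modeling of semistructured proteins and
    protein-RNA complexes. Generates rigid-body-arrangement ensembles
    consistent with nanometer-range distance-distribution restraints
    (e.g. from DEER/PELDOR EPR) by enumerated sampling of reference-point
    distance matrices and distance-geometry embedding; builds coarse-grained
    flexible peptide and RNA linkers between placed bodies; fits conformer
    populations against distance distributions and small-angle scattering
    curves with a loss-of-merit balancing scheme and block-iterative
    pruning; and analyzes ensembles for heterogeneous order via ensemble
    width, residue pair correlation, and local compaction (Flory scaling)
    matrices. Includes synthetic-data generators for planted rigid-body
    systems and random-coil and helix-coil ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
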