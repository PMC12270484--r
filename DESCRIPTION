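Package: ideaEnergy
Title: Interpretable Protein-DNA Energy Models from Complex Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns residue-level amino-acid by nucleotide interaction energy
    matrices from protein-DNA complex structures by maximizing the binding
    energy gap between native (strong-binder) sequences and randomized decoy
    sequences, relative to the decoy energy variance. The learned energy model
    predicts relative binding free energies for threaded protein/DNA sequence
    pairs, can be recalibrated against SELEX-style affinity tables by ridge
    regression, scans genomic sequence for binding sites via decoy-normalized
    Z-scores, and exports a sequence-specific tanh pair potential (with
    Debye-Hueckel electrostatic and excluded-volume companions) as tabulated
    input for coarse-grained simulation engines. Includes a synthetic-scenario
    generator (toy coarse-grained complexes, planted energy matrices, affinity
    tables, genomes with ground-truth sites) used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
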