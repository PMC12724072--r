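Package: ssaligner
Title: Lossless Approximate Read Alignment with Search Schemes over a
    Bidirectional FM-Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Aligns short sequencing reads to reference genomes losslessly,
    reporting every occurrence of a read within a user-chosen edit distance
    (up to 13 errors), or every optimal occurrence via strata. Reads are
    partitioned into parts and matched with search schemes executed over a
    bidirectional FM-index; edit distances are maintained with banded
    bit-parallel (Myers-style) alignment rows, with dynamic partitioning,
    dynamic scheme selection and in-text verification of sparse candidates.
    Supports single- and paired-end FASTQ/FASTA input with proper-pair
    resolution under an inferred fragment-size model, and writes SAM.
    Includes a deterministic synthetic-data generator (random genomes,
    reads with planted substitutions and indels, sidecar truth tables) so
    every component is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools
SystemRequirements: C++11
Config/testthat/edition: 3
RoxygenNote: 7.3.3
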