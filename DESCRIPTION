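Package: SilicoDigest
Title: In Silico Restriction Digestion of Genomes for Chromatin
    Fragmentation Assay Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting how a panel of restriction
    endonucleases fragments a genome. Models enzymes as IUPAC-degenerate
    recognition motifs, maps every recognition site across a FASTA
    assembly, derives the implied fragment intervals and their size
    statistics, detects regions refractory to digestion (fragments
    remaining above a size cutoff), classifies them against annotation
    tracks (assembly gaps, blacklists, repeats, chromatin-state
    segmentations), and compares predicted fragment sizes with observed
    paired-end template lengths. Includes a seeded synthetic-genome and
    fixture generator so every analysis is testable without external
    downloads. Designed for planning restriction-based chromatin
    fragmentation in low-input ChIP-seq assays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
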