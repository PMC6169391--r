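Package: traptag
Title: Analysis of piggyBac Promoter-Trap Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational side of piggyBac promoter-trap
    (gene-trap) screens in insect genomes. Detects reporter-fusion junctions
    in paired-end RNA-seq reads by exact-match classification, maps
    splinkerette PCR flanking fragments to TTAA insertion sites, annotates
    insertions against gene models (5'-UTR introns, coding introns, exons,
    UTRs) with distances to the ORF start, scores splice acceptors with a
    position conservation matrix, and computes screen-level statistics
    (remobilization frequencies, local-hopping and intron-position
    chi-square tests). Includes a synthetic-data generator that emulates a
    multi-scaffold genome, planted TTAA insertions, in-silico splinkerette
    fragments and chimeric fusion reads, with a machine-readable truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
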