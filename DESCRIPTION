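Package: atpossess
Title: Sequence Composition and Recruitment Analysis of Nucleoid-Associated
    Protein Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-peak-calling analysis of ChIP-seq data for AT-rich
    minor-groove binders such as the bacterial silencer H-NS. Computes
    summit-window AT content, genome-wide AT maps, dinucleotide and
    trinucleotide usage deviations and their Spearman correlation with
    recruitment (fold enrichment), binned AT-versus-recruitment curves
    with slope estimates, coverage metaprofiles around transcription
    start sites, differential peak-set comparison, and delta-delta-Ct
    quantification for ChIP-qPCR and qRT-PCR. Ships a synthetic
    genome/occupancy simulator with recorded ground truth so that every
    statistic can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
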