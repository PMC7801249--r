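Package: backsplice
Title: Plant Circular RNA Detection from Chiastic Split Reads
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects plant circular RNAs (circRNAs) from split-read RNA-seq
    alignments. Back-splice junctions are called from chiastic split reads,
    screened with plant-specific criteria (20 kb default / 100 kb maximum
    span, strict per-segment mismatch and alignment-score thresholds, 5-bp
    back-splice site adjustment, U2 GT-AG/GC-AG and U12 AT-AC splice
    signals, paired-end consistency), verified by re-screening raw reads
    against a pseudo-reference of junction flanks, and resolved to
    full-length isoform sequences using the gene annotation. Downstream
    modules predict miRNA cleavage targets and endogenous target mimics on
    circRNA sequences, test circRNA-mRNA pairs for shared-miRNA enrichment
    with a hypergeometric test, export circRNA-miRNA-mRNA networks, and
    assign candidate functions by GO enrichment of ceRNA partners. A
    built-in simulator generates synthetic genomes, annotations,
    junction-spanning reads and truth-derived split alignments for
    benchmarking with sensitivity/precision/F1 metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
biocViews: Transcriptomics, Annotation, Network, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
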