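Package: riboshift
Title: Length-Dependent Translation Bias and Gene-Set Shift Analysis for
    TRAP-seq Translatomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of cell-type-specific translatome (TRAP-seq)
    and proteome differential-expression tables: rank-based gene-set statistics
    (running-sum enrichment score with permutation nulls, mean-rank gene-set
    analysis, two-sample z tests against full or size-matched references), a
    CDS-length translation-bias framework (length bins with Kolmogorov-Smirnov
    tests, top-N up/down length comparisons, length-ranked gene-set analysis),
    GO-term sign-imbalance z scores with term-network construction and
    edge-betweenness clustering, and a CAGE-pileup transcription-start-site
    caller with 5'UTR assignment and exclusion rules. A synthetic-data
    generator emits gene universes, differential tables, paired count matrices
    and CAGE pileups with known ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: GeneExpression, Transcriptomics, RiboSeq, GeneSetEnrichment,
    Sequencing, Software
RoxygenNote: 7.3.3
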