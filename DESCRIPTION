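Package: poolsnv
Title: Pooled-Sample SNV Discovery and Cross-Pool Diversity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-nucleotide variant discovery from pooled
    transcriptome resequencing and for comparing nucleotide diversity across
    pools. Implements FASTQ read cleaning (missing-call, head-quality and
    3'-window trimming rules), pileup-based SNV calling under minimum-coverage,
    per-allele read-support and summed-quality thresholds, gene-feature (CDS/UTR)
    assignment and density summaries, per-pool major-allele-frequency statistics,
    shared and fixed-differential pool comparisons, the intron-distance and
    flanking-polymorphism marker filter cascade, genotyping-panel selection and
    polymorphism information content. A synthetic-data generator produces a toy
    genome, gene models, pool-structured truth variants and per-pool aligned
    exonic reads so the whole pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    withr,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    SummarizedExperiment
Config/testthat/edition: 3
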