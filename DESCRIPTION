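Package: epideg
Title: Predicting Differentially Expressed Genes from Histone
    Acetylation ChIP-Seq Features
Version: 0.1.0
Authors@R:
    person("Epideg", "Maintainers", email = "maintainers@epideg.org",
           role = c("aut", "cre"))
Description: Feature engineering and probabilistic classification to
    recover differentially expressed genes (DEGs) from histone-mark
    ChIP-seq signal. Quantifies normalized read densities over named
    gene-anatomy segments (promoter windows, UTRs, exons, introns, gene
    bodies), derives peak-based features (peak counts, sizes, fold
    enrichments, distances, and M-value differential peaks), selects
    features by information gain, ReliefF or correlation-based subset
    search, trains probability-emitting classifiers under stratified
    cross-validation, and ranks candidate genes by class probability with
    a bin-wise cumulative-precision cutoff. Includes a synthetic-data
    generator with planted mark-to-expression associations so the whole
    pipeline is testable end to end without external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    digest,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
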