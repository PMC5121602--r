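Package: neurogrn
Title: Chromatin-Association Integration and Gene Regulatory Network
    Construction for Neural Fate Acquisition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates transcription-factor chromatin association (ChIP-chip and
    ChIP-seq scored peak intervals) with histone-acetylation dependence and
    tissue-resolved expression to build directed transcription factor to target
    gene regulatory networks. Provides replicate consensus peak calling with FDR
    thresholding, control and knockdown peak subtraction, nearest-TSS gene
    assignment, genomic-feature fold-enrichment statistics, RPKM/z-score
    expression processing with tissue-enrichment classification, position weight
    matrix motif scanning with hypergeometric enrichment, 2x2 overlap statistics
    (chi-square with Yates' correction), and a synthetic-data generator with
    planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
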