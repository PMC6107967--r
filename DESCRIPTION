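Package: nascentr
Title: Nascent RNA Sequencing Analysis of Gene Transcription and Enhancer Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of strand-specific nascent RNA sequencing data (GRO-seq,
    PRO-seq). Quantifies RNA polymerase distribution over annotated genes
    (promoter-proximal pausing, gene-body transcription), tests
    condition-dependent changes with a negative-binomial model under
    median-of-ratios normalization, detects transcribed enhancers from
    bidirectional intergenic transcription, links enhancers to candidate
    target genes by four strategies, and prioritizes enhancers by combining
    ChIP-seq binding evidence with transcriptional-change evidence. Includes
    a deterministic simulator of desk-scale datasets with planted paused
    genes and enhancers for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    graphics,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
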