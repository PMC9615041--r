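Package: atacwave
Title: Time-Course Chromatin Accessibility Dynamics from ATAC-Seq Peak Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of replicated ATAC-seq time courses over an evolving
    cell population: negative-binomial Wald tests for differential
    accessibility between consecutive timepoints (median-of-ratios
    normalization, trended dispersion shrinkage, Benjamini-Hochberg
    adjustment), a Gaussian-process likelihood-ratio test that classifies
    each peak's standardized temporal profile as dynamic or static,
    mixture-of-Gaussian-processes clustering of dynamic profiles into
    temporal archetypes, two-proportion Z tests comparing the annotation
    composition of dynamic versus static peaks, and local preranked
    gene-set enrichment with detection of gene sets whose enrichment sign
    reverses between the selection-onset and selection-release transitions.
    A synthetic-data generator produces toy genomes, peak sets, gene sets
    and replicated negative-binomial count matrices with known dynamic and
    differential ground truth so that the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    fgsea,
    mclust,
    optparse,
    pracma
Config/testthat/edition: 3
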