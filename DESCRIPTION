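Package: promusage
Title: Alternative Promoter Usage Quantification from Spliced RNA-Seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies alternative promoter (first-exon) usage of multi-isoform
    genes from spliced RNA-seq alignments. Derives isoform-discriminating
    first-exon regions from gene models, counts supporting reads with
    configurable alignment policies, normalizes to reads per million, computes
    per-sample promoter usage proportions and compares them between groups with
    Welch t-tests. Also provides the surrounding expression stage (median-of-ratios
    size factors, FPKM/TPM, expressed-gene filtering, fold-change based
    differential-expression calls, DEG set algebra), hypergeometric term
    enrichment with Benjamini-Hochberg correction and richness factors, and a
    synthetic-data generator (gene models, spliced alignments from known isoform
    mixtures, negative-binomial count matrices, annotation maps) with
    machine-readable truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
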