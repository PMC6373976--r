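Package: intratss
Title: TSS Cluster Calling and Intragenic TSS Analysis from 5'-Tag Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls transcription start site (TSS) clusters from stranded
    per-base 5'-tag count tracks using a per-genotype candidate support rule,
    annotates clusters through a fixed feature-priority hierarchy
    (intergenic < antisense < intron < exon < threeUTR < fiveUTR < proximal <
    promoter), classifies them by genotype contrast (basal, wild-type-specific,
    mutant-specific), quantifies cluster expression (CPM, log2, replicate
    concordance, promoter-expression contrasts), and aggregates chromatin
    signal around anchor positions (windowed medians, metagene profiles,
    seeded exonic control sampling, Wilcoxon contrasts). A synthetic TSS-seq
    generator plants known promoter and intragenic TSS architecture with
    negative-binomial tag counts so the whole pipeline is testable end to end
    against recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
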