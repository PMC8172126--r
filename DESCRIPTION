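Package: lncnet
Title: Integrated lncRNA-mRNA Transcriptome Analysis and ceRNA Network Inference
Version: 0.1.0
Authors@R:
    person("Bao", "Wen", email = "bwen.dev@example.org", role = c("aut", "cre"))
Description: Tools for integrated long non-coding RNA (lncRNA) and mRNA
    transcriptome analysis in staged bulk RNA-seq designs: novel-transcript
    filtering and consensus lncRNA calling, positional classification of
    lncRNAs (intergenic, bidirectional, intronic, antisense,
    sense-overlapping), FPKM normalization with a documented stand-in
    differential-expression test and Benjamini-Hochberg FDR, hypergeometric
    over-representation analysis, gene set enrichment analysis with
    signal-to-noise ranking and class-label permutation, antisense/cis/trans
    lncRNA target prediction, and competing endogenous RNA (ceRNA) network
    inference via a shared-miRNA hypergeometric sponge test. A synthetic-data
    generator with planted ground truth (negative-binomial counts, planted
    differential effects, planted positional classes and ceRNA triplets)
    makes every stage testable without sequencing data.
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
    rtracklayer,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
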