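Package: dmrscan
Title: Windowed Differential Methylation Analysis for Whole-Genome
    Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome bisulfite sequencing
    (WGBS) methylomes of non-model organisms.  Classifies cytosines into
    CG, CHG and CHH sequence contexts from a reference genome, calls
    methylated sites by a binomial test against the bisulfite
    non-conversion rate, summarises methylation per genomic element and
    as binned metagene profiles, detects differentially methylated
    regions (DMRs) by a 200 bp tiled genome scan with Fisher's exact
    test and Benjamini-Hochberg correction under context-specific
    filters, annotates DMR-associated genes with hypergeometric gene-set
    enrichment, computes FPKM and calls differentially expressed genes,
    and integrates methylation with expression through methylation-class
    assignment, Spearman correlation and a DMR-direction by
    DEG-direction concordance table.  A fully seeded synthetic-data
    generator produces genomes, annotations, replicated bisulfite count
    tables with planted DMRs, and methylation-coupled expression so the
    whole pipeline can be exercised and validated without sequencing
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
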