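Package: neurotrace
Title: Analysis of Tumour-Innervating Neuron Transcriptomes and Their
    Microenvironment Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for the downstream analysis of traced
    peripheral-neuron single-cell RNA-seq together with droplet-based
    tumour-microenvironment data: quality control, size-factor
    normalization, correlation-based label transfer against a reference
    atlas, SNN/Louvain clustering, pseudobulk negative-binomial Wald
    differential expression with a per-cell Wilcoxon fallback, consensus
    up/down signature construction across neuronal subpopulations,
    weighted Kolmogorov-Smirnov gene-set enrichment with a gene-set
    permutation null, and ligand-receptor interaction-potential scoring
    between neurons and microenvironment cell types. Ships a seeded
    synthetic-data generator with recorded ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    fgsea,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
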