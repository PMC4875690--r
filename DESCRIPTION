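Package: popcnv
Title: Population Copy Number Variation Analysis from Binned Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Detects copy number variants (CNVs) from binned whole-genome
    read depth, merges per-sample calls into cross-sample CNV regions
    (CNVRs), and scans for population-differentiated regions with the V_ST
    statistic and Student's t-test. Includes GC-bias correction, mean-shift
    multi-bandwidth segmentation, the q0 mappability / significance /
    length call filters, gene-content annotation with hypergeometric
    term-enrichment testing, a random-placement permutation test for
    CNVR-segmental-duplication association, delta-delta-Ct qPCR copy
    number and cv% concordance validation math, windowed copy-number
    heatmap profiles, and a fully seeded multi-sample cohort simulator
    with planted CNV truth sets for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    grDevices,
    jsonlite,
    pheatmap,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
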