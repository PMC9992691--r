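Package: loopscape
Title: 3D Enhancer Network Analysis for Hi-C and HiChIP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of three-dimensional enhancer networks from
    chromosome-conformation data. Provides insulation-score TAD boundary
    calling from binned contact matrices, significance calling of 10 kb
    HiChIP bin-pair interactions with coverage-bias correction and a
    distance-stratified background, regulatory-element annotation of loop
    anchors including ROSE-style super-enhancer stitching, a negative-binomial
    differential engine for loop counts, anchor acetylation signal and gene
    expression with threshold-based classification into gained/lost/constant
    loops and inducible/repressed/constitutive enhancers, assignment of
    gene-enhancer-loop triplets to six regulatory modes, cross-boundary loop
    analysis, virtual 4C track extraction, Fisher region-set enrichment,
    Louvain community analysis of anchor-loop graphs, and a synthetic-data
    generator with machine-readable planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
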