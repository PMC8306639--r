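Package: rhizonet
Title: Co-Occurrence Networks and Diversity Analysis for Rhizosphere
    Microbiome OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reusable pipeline for amplicon-based soil and rhizosphere
    microbiome studies: OTU table input/output and cross-marker merging,
    table-level denoising (negative-control OTU removal, relative-abundance
    filtering, rarefaction by subsampling without replacement), alpha
    diversity (Chao1, Shannon, Simpson, Hill evenness), Bray-Curtis
    dissimilarity, permutation-based multivariate analysis of variance
    (PERMANOVA) with sequential sums of squares, core-microbiome set
    partitions, and a permutation-calibrated Pearson co-occurrence network
    with Benjamini-Hochberg edge calling, hub (keystone) scoring, and global
    graph metrics. A synthetic count generator with planted correlation
    structure and group effects provides ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    biomformat,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
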