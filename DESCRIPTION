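Package: vesselmark
Title: Cross-Platform Meta-Analysis of Blood and Lymphatic Endothelial
    Expression Signatures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pooled cross-platform microarray meta-analysis of
    blood (BEC) versus lymphatic (LEC) endothelial cell expression profiles.
    Merges per-platform log2 expression matrices on canonical gene
    identifiers, filters genes by a minimum fraction of observed values,
    and removes inter-platform differences by gene-wise median centering
    and standard-deviation scaling. Differential expression between cell
    classes uses the Welch unequal-variance t-test with robust false
    discovery rate estimation (pi0 = min(1, 2*mean(p)) with step-up
    q-values) and inclusive fold-change/q-value thresholds. Marker lists
    from multiple studies are compared through exact n-way Venn partitions,
    and samples are embedded by classical (Torgerson) multidimensional
    scaling of Euclidean distances. A seeded simulator generates
    multi-platform datasets with planted marker genes, per-gene platform
    offsets, hybrid blood/lymphatic cell-line profiles and missingness, so
    the whole pipeline is testable without external downloads. Small
    laboratory statistics (specific median fluorescence intensity,
    transmigration percentage, reference-normalised adhesion counts) are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
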