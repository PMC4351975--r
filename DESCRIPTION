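Package: conetdiff
Title: Differential Co-Expression Network Analysis Between Two Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrative two-cohort co-expression network analysis for
    transcriptomic studies: probe filtering and covariate adjustment,
    two-group differential expression, per-transcript trait correlation
    screening with FDR, weighted co-expression network construction
    (soft-threshold power adjacency, topological overlap, average-linkage
    clustering with a tree-variant dynamic cut), module eigengene and
    module-trait statistics with permutation FDR, modular differential
    connectivity between cohorts with a dual-permutation FDR, cross-network
    module overlap and gene-signature enrichment by Fisher's exact test,
    and per-module mutual-information networks with data-processing-
    inequality pruning and key-driver nomination. Includes a synthetic
    two-cohort generator with planted modules, trait effects, differential
    connectivity and differential expression for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
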