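Package: desiccatR
Title: Desiccation-Tolerance Analysis Toolkit for Natural Drosophila Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for analysing desiccation tolerance in
    natural fly populations. Implements interval-censored probit estimation of
    lethal times (LT50/LT100) from periodic mortality checks, climate and
    environment association with variance-inflation-factor pruning,
    ordered-gene-list (transcriptogram) sliding-window differential expression
    with cluster calling and hypergeometric enrichment, protein-protein
    interaction hub ranking by maximal clique centrality, tRNA-derived-fragment
    (tRF) target prediction by seed-anchored duplex minimum-free-energy
    scoring, transposable-element proximity enrichment with post hoc residual
    diagnostics, and physiology plus cuticular-hydrocarbon statistics.
    A seeded synthetic-data module generates every input with the statistical
    structure the analyses assume, so the full pipeline is exercisable and
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    edgeR,
    limma,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    lme4,
    jsonlite,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
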