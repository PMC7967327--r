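Package: genoRules
Title: Association Rule Mining of Higher-Order Genetic Risk Patterns in
    Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers and characterizes higher-order combinations of
    genetic risk variants in case-control studies by association rule
    mining. Genotypes are encoded as a binary incidence matrix under a
    dominant model (with optional absence-coded protective alleles), rules
    with the disease as consequent are mined level-wise with support and
    confidence thresholds, and mined patterns are characterized with crude
    and covariate-adjusted odds ratios, bias-corrected bootstrap
    confidence intervals, Bonferroni correction, and additive
    (RERI/attributable proportion) and multiplicative interaction
    decompositions. Includes a synthetic-cohort simulator with planted
    multi-variant risk patterns, population substructure and missingness,
    plus rule-set summaries and bipartite rule-item network export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    igraph,
    ranger,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
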