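Package: rcmir
Title: miRNA Co-Expression Networks by Mutual Information with
    Clustering-Coefficient Threshold Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for small-RNA sequencing count data from
    perturbation experiments: median-of-ratios normalization, a simplified
    negative-binomial Wald test for differential expression, mutual-information
    similarity between discretized miRNA expression profiles, data-driven
    similarity-threshold selection by comparing the network clustering
    coefficient against its random-graph expectation, connected-component
    cluster extraction, cluster common-target identification with
    hypergeometric gene-set enrichment, efficiency-adjusted qPCR relative
    expression ratios, and growth-phenotype arithmetic (percent reduction,
    population doubling time, coefficient of variation, linear calibration
    curves). Includes a seeded synthetic-data generator producing
    negative-binomial counts with planted latent-factor co-expression clusters
    and fold-change effects for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
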