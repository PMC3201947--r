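Package: gwasnet
Title: Pathway- and Network-Oriented Analysis of GWAS Association Results
Version: 0.1.0
Authors@R: person("gwasnet", "developers", role = c("aut", "cre"),
    email = "gwasnet-maintainers@example.org")
Description: Combines single-nucleotide polymorphism (SNP) association
    p-values with functional annotation to compute weighted gene-level
    scores, searches a protein-protein interaction network for active
    sub-networks enriched in disease-associated genes, performs
    hypergeometric gene-set enrichment with Bonferroni correction and
    kappa-statistic term grouping, and provides degree-distribution
    diagnostics (power-law fit, Erdos-Renyi randomization). Includes a
    synthetic-data generator with planted modules and enriched terms so
    the whole pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
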