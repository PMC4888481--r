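Package: toxnet
Title: Seed-Induced Genetic-Interaction Subnetwork Topology and
    Slow-Growth Signature Analysis
Version: 0.1.0
Authors@R:
    person("Toxnet", "Maintainers", email = "maintainers@toxnet.example.org",
           role = c("aut", "cre"))
Description: Tools for the computational analysis of chemogenomic
    toxin-sensitivity screens in yeast. Extracts seed-induced subnetworks
    from a genome-scale genetic-interaction network, characterizes their
    largest connected component (global clustering coefficient, average
    path length, diameter, parametric sphere-based graph entropy and the
    derived information-theoretic distance), and assesses significance
    against a seed-resampling permutation null. Includes exact
    hypergeometric gene-set overlap tests with Benjamini-Hochberg
    adjustment, expression-matrix processing (quantile normalization,
    duplicate-probe averaging, fold-change filtering, signed-log
    differences, correlation-based hierarchical clustering) with
    slow-growth-signature scoring, synthetic-data generators with
    ground-truth bookkeeping, and an end-to-end pipeline with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    ape
Config/testthat/edition: 3
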