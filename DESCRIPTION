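Package: netpharm
Title: Network Pharmacology of Multi-Herb Formulae
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible network-pharmacology pipeline for multi-herb
    formulae. Predicts compound targets by the concordance between a
    compound's chemical similarity to reference drugs and each gene's
    network closeness to those drugs' known targets, assembles a tripartite
    herb / putative-target / known-disease-target network over a
    protein-protein interaction backbone, identifies major nodes by the
    all-above-median rule on degree, betweenness, closeness and k-coreness,
    performs hypergeometric pathway over-representation analysis with
    Bonferroni correction, and scores per-herb target reliability by hit
    times and rank order. Includes a fully seeded synthetic-data generator
    with planted compound-target signal and a planted enriched pathway so
    that every stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
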