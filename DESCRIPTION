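Package: tcmnp
Title: Systems-Pharmacology Network Analysis of Multi-Herb Medicines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for network-pharmacology studies of
    multi-herb traditional medicines: literature-based herb-disease
    association testing (upper-tail hypergeometric), ADME candidate
    screening by oral bioavailability and Tanimoto drug-likeness
    thresholds with an auditable rescue list, dual-threshold RF/SVM
    consensus acceptance of compound-target interactions, bipartite
    compound-target and target-pathway network construction with
    degree-based Jun-Chen-Zuo-Shi herb-role classification,
    physicochemical descriptor group comparison, and gene-set
    over-representation analysis. Ships transcribed study tables for a
    20-herb breast-cancer case and seeded synthetic-data generators so
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
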