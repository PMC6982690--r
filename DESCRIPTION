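Package: herbnetscreen
Title: Network-Pharmacology Screening for Herb-Pair Compound, Target, and
    Pathway Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, offline re-implementation of the systems-pharmacology
    screening workflow used to dissect multi-compound, multi-target herbal
    formulas: per-herb compound tables are merged and deduplicated, joined to
    compound-target interaction tables, and intersected with disease gene sets
    to yield active compounds and potential targets; the target list is tested
    for pathway and GO over-representation with an exact hypergeometric tail
    and Benjamini-Hochberg adjustment; compound-target-disease, target-pathway,
    and protein-protein interaction networks are built and scored with degree,
    betweenness, and closeness centrality; and key compounds, hub genes, and
    key pathways are screened with strict above-average centrality rules. A
    seeded synthetic-data generator emulates the database-derived inputs so
    every stage is testable without live database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
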