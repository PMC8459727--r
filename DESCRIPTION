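Package: pathconsensus
Title: Cross-Database Consensus for Pathway Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Runs over-representation analysis (one-sided Fisher's exact
    test with Benjamini-Yekutieli correction) and gene set enrichment
    analysis (two-group and pre-ranked, with permutation-based NES, nominal
    p and FDR q) against multiple pathway gene-set databases, merges
    equivalent pathways across databases into a meta-database via curated
    equivalence mappings, assembles and validates the is-part-of pathway
    hierarchy as a directed acyclic graph, classifies each group of
    equivalent pathways as concordant or contradictory (including conflicts
    in the sign of the normalized enrichment score), and decomposes
    disagreements at the gene level through Venn-region analysis annotated
    with fold changes. Includes a synthetic-data module that generates
    overlapping gene-set collections with known equivalence structure and
    two-group expression matrices with planted pathway signal, plus a
    command-line interface over the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
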