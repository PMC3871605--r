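Package: ruminet
Title: Differential Expression, Category Enrichment and Co-Expression
    Networks for Two-Condition Transcriptome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A small, reproducible pipeline for two-condition microarray-style
    expression studies with very few replicates, as used in ruminant nutrition
    transcriptomics. Selects differentially expressed genes by fold change and
    false discovery rate, performs flat gene-category (GO-style) enrichment
    with a two-sided Fisher's exact test, a Pearson chi-squared companion test,
    an empirical Fisher-versus-chi-squared false discovery rate and the
    enrichment ratio Re, and builds per-condition signed Pearson co-expression
    networks with degree centrality, k-core decomposition and cross-condition
    core-regulator ranking. Includes a synthetic-data generator with planted
    differential genes, correlated gene modules and enriched annotation
    categories so every stage can be validated against known truth, plus a
    2^-ddCt relative-quantification helper for qPCR follow-up.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
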