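Package: miRstress
Title: Sex-Specific miRNA-mRNA Integration Analysis for Stress Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for paired small-RNA and mRNA sequencing
    count data from factorial sex-by-stress designs. Provides count filtering,
    voom-style precision weights with empirical-Bayes moderated tests and
    per-sex stress contrasts, directional gene-list overlap testing by exact
    hypergeometric tails against a fixed background, dual-source miRNA target
    intersection, per-miRNA chi-squared enrichment of target direction
    frequencies with Benjamini-Hochberg selection, signed bipartite
    miRNA-mRNA network construction with Cytoscape-compatible export,
    Fisher's exact overrepresentation analysis against gene-set collections,
    and delta-delta-Ct qPCR validation with outlier handling. A synthetic
    data generator emulates pooled-library negative-binomial experiments with
    sex-specific effects and planted anti-correlated miRNA-target coupling,
    so the full pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    xml2
biocViews: GeneExpression, DifferentialExpression, Network, miRNA,
    Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
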