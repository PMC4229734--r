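Package: pmaxnet
Title: Context-Specific Interactome Filtering with Expression Specificity
    and Percent-of-Maximum Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates interactome and transcriptome data to identify
    tissue- or stage-specific molecular networks. Normalizes gene x
    condition expression tables onto an expression-specificity (Es) scale
    and a percent-of-maximum (pmax) scale, classifies genes as ubiquitous,
    specific, or neither (NUNS), quantifies interaction tendencies of gene
    classes in protein-protein and transcription-factor-target networks
    against size-matched random sets and degree-preserving nulls with
    Monte-Carlo binomial-confidence p-values, extracts context-relevant
    subnetworks by pmax filtering, and scores gene lists and subnetworks by
    annotation-term enrichment with hierarchical clustering of contexts. A
    synthetic-data generator with planted gene classes, edge propensities,
    and annotation structure makes every stage testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
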