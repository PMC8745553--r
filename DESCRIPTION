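Package: implinet
Title: Boolean Implication Networks for Multi-Omics Gene Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers Boolean implication networks between discretized gene
    expression and copy-number states using prediction-logic scope and
    precision statistics, and assembles them into a multi-omics network
    around a seven-gene non-small cell lung cancer prognostic signature.
    Includes housekeeping-gene-calibrated three-level discretization of
    expression matrices, cross-cohort rule intersection, CRISPR/RNAi
    dependency-screen standardization and proliferation-gene calling,
    proportional-hazards risk-score survival stratification, IC50/EC50
    drug-response categorization with differential-expression filtering,
    construction of up/down gene lists for connectivity-map queries, and
    seeded synthetic-data generators with planted ground truth for
    end-to-end validation.
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
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
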