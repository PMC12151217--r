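Package: rasrules
Title: Point-Based ACMG/AMP Variant Classification for RASopathy Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic rules engine implementing the ClinGen RASopathy
    expert-panel specifications of the ACMG/AMP germline variant
    classification framework for sixteen Ras/MAPK-pathway genes. Structured
    per-variant evidence (proband, family, population-frequency, functional,
    computational and in-trans observations) is scored criterion by criterion
    with point-based strength scaling for the case-observation codes
    (PS2/PM6, PS4, BS2, BP2/BP5), threshold criteria (filtering allele
    frequency with exact binomial confidence bounds, REVEL cutoffs, assay
    counting, hotspot and paralogous-residue logic), routed through the LZTR1
    dual-mechanism decision tree, and combined into a five-tier clinical
    classification with gene-validity capping. A companion scorer implements
    the case-level point rules used for gene-disease validity curation, and a
    seeded synthetic-evidence generator provides independent oracles for
    testing.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
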