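Package: bap1tools
Title: Multi-Caller Somatic Variant Integration and Expression-Based
    BAP1 Activity Scoring
Version: 0.1.0
Authors@R:
    person("BAP1 Tools", "Developers", email = "bap1tools@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing disruption of a tumor suppressor gene
    (BAP1 by default) from multi-omic cancer cohort data. Merges somatic
    variant calls from multiple callers at the MAF level, applies read-support
    filtering (variant allele frequency and alternate read count), integrates
    gene-level copy-number loss into per-sample alteration categories, builds
    a direction-weighted expression signature from differential-expression
    results, scores samples by weighted and rank-based activity scores,
    classifies samples as mutant-like or wildtype-like with a two-component
    Gaussian mixture, and ships negative-binomial synthetic-data generators
    with known ground truth so the whole pipeline can be validated without
    any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
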