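Package: lipidstress
Title: Downstream Shotgun-Lipidomics Analysis of a Corticosterone Stress Study
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream statistical analysis of shotgun-lipidomics
    quantification tables from a corticosterone-induced stress /
    antidepressant study in rats. Parses lipid shorthand nomenclature
    (class, total acyl carbons, double bonds, ether and lyso flags),
    applies identification and limit-of-detection filters, normalizes
    amounts to mol% per total lipids, computes structural summary
    statistics (mol%-weighted average double bonds and chain length,
    saturated/unsaturated class partitions) with one-way ANOVA and
    Holm-Sidak follow-up, fits per-lipid one-factor linear models with
    five treatment contrasts and per-contrast Benjamini-Hochberg FDR,
    and correlates lipid species with forced-swim-test behavior by
    Spearman rank correlation. Includes a synthetic-data generator that
    emulates the study design (six treatment arms, two tissues,
    lognormal abundances with LOD censoring, dose-ordered
    lysophosphatidylethanolamine effects, behavior coupling) so the
    whole pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr
Config/testthat/edition: 3
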