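Package: midflux
Title: Stable-Isotope Tracing and Bioenergetics Analysis for Muscle Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for steady-state stable-isotope infusion
    experiments and tissue bioenergetics. Provides natural-abundance
    correction of GC-MS mass-isotopolog distributions by non-negative least
    squares, fractional enrichment and total-labeling summaries, a
    deuterium-lactate mixing model that partitions tissue lactate between
    circulatory import and intramuscular pyruvate, circulatory turnover flux
    (Fcirc) from infusion rate and plasma enrichment, ex vivo glycolytic rate
    estimation against an internal standard, isolated-mitochondria
    respirometry states and respiratory control ratio, adenylate energy
    charge, 2^-ddCt relative quantification, and a normality-routed group
    statistics workflow with Bonferroni correction. A synthetic-cohort
    generator emulates the infusion arms, plate traces and metabolome tables
    the pipeline consumes, so every estimator is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    multcomp,
    quadprog,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
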