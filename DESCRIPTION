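Package: oncoclassify
Title: Rule-Based Biological and Clinical Classification of Somatic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, auditable rule engine for the two-level
    classification of somatic variants detected by targeted NGS in solid and
    haematological tumours. Variants are first assigned a tumour-independent
    biological class (Benign, Likely Benign, VUS, Likely Pathogenic,
    Pathogenic) by a fixed workflow: technical filtering, population-frequency
    screening against ethnic-specific minor allele frequencies, matching
    against curated consensus pathogenic variant (hotspot) lists, routing of
    clear loss-of-function variants by tumour-suppressor/oncogene role, and a
    four-parameter evidence scoring table, together with a small set of
    gene-specific exception rules (TP53, BRCA1/2, CALR, NPM1, CEBPA, MET).
    Biological classes are then mapped onto the four-tier ACMG/AMP clinical
    system under hard consistency constraints, and clinical reports are
    rendered with the associated content rules. Every decision carries an
    ordered rule trail for audit. A seeded fixture generator produces
    synthetic variant batches with construction-time truth labels covering
    every rule, so the whole engine is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
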