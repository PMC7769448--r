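Package: barcodegap
Title: Gap Analysis of DNA-Barcode Reference Libraries Against Regional
    Species Checklists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Audits a DNA-barcode reference library (BOLD-style specimen
    records with Barcode Index Numbers) against a regional species
    checklist (OBIS-style occurrence lists). Validates names to
    species-level binomials, resolves synonyms through a WoRMS-style
    synonym table, matches each valid name and its synonym sub-list
    against barcode records, classifies species by barcode availability
    (none, private-only, public) and geographic provenance (collected
    inside or outside the focal region), grades publicly barcoded
    species into BIN-concordance annotation-quality classes (A/B, C, D,
    E*, E**, F), and reports per-group coverage tables, exclusive
    country-combination shared-species counts, and plot-ready point
    exports. Includes a synthetic-universe generator that plants
    recoverable truth for every downstream statistic.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
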