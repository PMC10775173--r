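Package: hemvar
Title: ACMG/AMP Interpretation of F8 and F9 Variants in Hemophilia Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clinical interpretation of coagulation factor VIII (F8)
    and factor IX (F9) variants in hemophilia A/B cohorts. Parses HGVS-style
    coding and protein descriptions, maps coding positions onto packaged
    transcript and protein-domain models, assigns ACMG/AMP evidence codes with
    strength modulation (NMD-aware PVS1, case-count-banded PS4, REVEL and
    SpliceAI evidence bands, activity-gated PP4), and combines evidence into
    P/LP/VUS/LB/B calls by either a points system or the categorical combining
    rules. Also provides patient-level derivations (severity banding, Bethesda
    units), cohort summary tables (variant spectrum, inhibitor incidence,
    inheritance, prenatal outcomes), a seeded synthetic-cohort generator, and
    TSV readers/writers with a thin command-line interface.
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
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
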