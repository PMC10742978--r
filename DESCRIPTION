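Package: dentage
Title: Dental Age Estimation from Developmental Tooth Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Table-driven implementations of three dental age estimation
    methods used in forensic odontology: Nolla's ten-stage calcification
    method, Demirjian's seven-tooth maturity score with the Olze
    third-molar supplement, and London-Atlas-style whole-dentition
    pattern matching.  Includes the accompanying accuracy-evaluation
    pipeline (signed and absolute estimation error, per-age-category
    aggregation, margin-based correct-estimation rates, paired
    comparisons between methods) and a synthetic cohort simulator that
    generates staged dentitions with known chronological ages together
    with self-consistent reference tables, so the whole system can be
    exercised end to end without radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
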