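Package: carcwoe
Title: Weight-of-Evidence Prediction of Rat Carcinogenicity from
    Subchronic Histopathology and Pharmacological Class
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based weight-of-evidence categorization of non-genotoxic
    pharmaceuticals with respect to their rat carcinogenic potential. Compounds
    are first categorized from subchronic (3- and/or 6-month) histopathology
    (putative preneoplastic hyperplasia versus 2-year tumor outcome), then from
    transcribed pharmacological class decisions, and finally combined into a
    single call. Ships a 289-compound reference dataset with controlled organ
    and lesion vocabularies, a human-relevance filter for rat tumor types,
    diagnostic predictivity metrics (sensitivity, specificity, positive and
    negative predictivity, false-negative fraction), and a seeded synthetic
    compound generator for parameter-recovery simulation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
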