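Package: screenburden
Title: Economic Burden of Cancer Screening from Insurance Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the treatment-cost burden induced by
    population-level upper gastrointestinal cancer screening from
    insurance-claims-style records of a two-arm trial. Verifies treated
    cancer cases from hospitalization claims, harmonizes staggered-enrollment
    arms into a uniform-follow-up cohort with a standard observation window,
    values costs from the patient and societal perspectives (out-of-pocket,
    hospitalization, and human-capital time costs with discounting, medical
    CPI adjustment, and purchasing-power-parity conversion), classifies
    catastrophic health expenditure, and produces arm-level comparison
    tables, accumulated-cost curves, and expense-classification breakdowns.
    Includes a calibrated synthetic claims generator so the full pipeline
    runs and is testable without access to confidential claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
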