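Package: ctrreport
Title: Results and Outcome Reporting Analysis for Clinical-Trial Registries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for meta-analysis of results deposition and outcome
    reporting in ClinicalTrials.gov-style trial registries. Parses registry
    XML records, classifies lead sponsors into five institutional classes
    (edu, com, gov, hos, col) with a prioritised multilingual keyword
    dictionary and agency-class fallback, evaluates the cascade of
    results-deposition requirements (completion, FDA regulation, Section 801,
    phase 2-4, publication, interventional design), and computes reporting
    efficiency tables plus odds ratios with confidence intervals per sponsor
    class. Includes a seeded synthetic registry generator calibrated to the
    composition of the public registry as of early 2012, so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    stringi,
    xml2,
    yaml,
    readr,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
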