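Package: peaescreen
Title: Screening Narrative Hospital Charts for Pulmonary Embolism as an
    Adverse Event
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A text-mining pipeline for detecting pulmonary embolism
    occurring as a hospital-acquired adverse event (PEAE) from narrative
    electronic medical records. Charts are reduced to candidate evidence by
    note chunking with keyword or embedding-similarity filters, discharge
    summaries are parsed into six clinical sections through a generation
    backend, and a dialect-aware prompt plus a first-sentence yes/no
    heuristic yields a binary screen per admission. Includes a deterministic
    rule-based mock generation backend, a synthetic gold-labelled chart
    corpus generator with configurable confounders, and an evaluation layer
    with bootstrap confidence intervals, an ICD-code rule baseline, cohort
    summaries, and population-level surveillance trend scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
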