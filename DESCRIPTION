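Package: quotecross
Title: Quoted-Speech Extraction and Case-Crossover Analysis for Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects quoted-speech spans in clinical free text using a
    rule-based scanner (apostrophe/contraction disambiguation, subquotation
    absorption, runaway-quote guard, email/URL filtering), scores extractions
    against gold span annotations, builds case-crossover matched pairs from
    ICD-coded hospital admissions and per-patient document streams, and fits
    1:1 matched-pair conditional logistic regression from the conditional
    likelihood. Includes a seed-reproducible synthetic electronic-health-record
    simulator so the whole pipeline is testable without patient records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
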