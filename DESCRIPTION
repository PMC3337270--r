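Package: adesignal
Title: Testing Drug-Safety Signals in Free-Text Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Lexicon-based concept annotation of free-text clinical notes with
    NegEx-style negation detection, construction of temporally ordered patient
    timelines merged with coded ICD-9 diagnoses, classification of patients into
    2x2 contingency cells by the temporal ordering of first mentions of a
    condition, a drug and an adverse event, and disproportionality statistics
    (odds ratio, Woolf confidence interval, Fisher's exact test) for testing
    hypothesized condition-drug-event safety signals. Includes a synthetic
    note-corpus generator with planted temporal patterns, negated decoys and
    controllable noise so the full pipeline can be validated end to end without
    access to protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
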