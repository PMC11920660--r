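Package: sympner
Title: Symptom Mention Extraction and Polarity Classification for Narrative Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for extracting disease and symptom mentions
    from short narrative clinical text (such as the subjective field of
    SOAP-format pharmaceutical care records) and classifying each mention as
    affirmed or denied.  Provides full-width text normalization and sentence
    segmentation for Japanese clinical notes, standoff-annotation input and
    output, a character-level linear-chain conditional random field tagger
    with a pluggable emission contract, an entity-level evaluator with
    Levenshtein partial matching and a four-category error taxonomy,
    cross-validated learning curves with power-law extrapolation of the
    F1-score against training-set size, and a synthetic corpus generator with
    controlled error injection so every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
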