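Package: factframe
Title: Frame-Semantics Information Extraction for Mammography Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A schema-driven framework for extracting structured clinical
    facts from free-text mammography reports. Facts are frames with one
    anchor entity and optional modifier entities; extraction runs as a
    two-step pipeline (span extraction per fact type, then token-level
    entity labeling inside each span) over pluggable backends, followed by
    template filling and dictionary-based terminology normalization.
    Includes corpus curation (cleaning, abbreviation-aware sentence
    splitting, BI-RADS-stratified diversity sampling, pretraining splits),
    conversion of gold annotations to extractive question-answering and
    IOB training formats, a full evaluation suite (unitizing
    inter-annotator agreement, span exact-match/F1, entity-level
    precision/recall/F1, perplexity, precision tallies, bootstrap
    confidence intervals, k-fold planning, embedding-based corpus
    similarity), and a seeded generator of BI-RADS-conditioned synthetic
    reports with exact gold annotations so every component is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
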