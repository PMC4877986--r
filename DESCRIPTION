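Package: plscore
Title: Adherence Scoring for Plain Language Summaries of Systematic Reviews
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures how well plain language summaries (PLSs) of systematic
    reviews follow the PLEACS reporting standards. Provides rule-based
    detectors for the 14 measurable checklist items (title restatement, word
    count, jargon, heading structure, search date, search-strategy leakage,
    population details, study and participant counts, unexplained statistics,
    and quality/GRADE statements), a configurable point-based adherence score
    with conditional applicability for empty reviews and narrative summaries,
    corpus-level adherence tables, band distributions and per-group summaries,
    and a publication-time trend analysis. A seeded synthetic-corpus generator
    emits labelled PLS texts so extraction, scoring and trend recovery can be
    validated end to end without real review data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
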