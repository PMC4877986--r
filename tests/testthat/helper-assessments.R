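# random but invariant-respecting assessment tibbles, for property tests
# (applicability: items 9-14 NA iff empty review, items 5-6 NA iff narrative,
# GRADE => quality)
random_assessments <- function(n) {
  empty <- runif(n) < 0.15
  structured <- runif(n) < 0.4
  missing <- ifelse(structured, sample(0:5, n, replace = TRUE), NA_integer_)
  rand_list <- function(pool, p_any) {
    lapply(runif(n) < p_any, function(has) {
      if (has) sample(pool, sample(1:2, 1)) else character(0)
    })
  }
  q13 <- runif(n) < 0.5
  q14 <- q13 & runif(n) < 0.3
  tib <- tibble::tibble(
    doc_id = sprintf("R%05d", seq_len(n)),
    is_empty_review = empty,
    item1_title_same = runif(n) < 0.5,
    item2_word_count = sample(c(0:900), n, replace = TRUE),
    item3_jargon = rand_list(c("outcome", "efficacy", "literature"), 0.5),
    item4_structured = structured,
    item5_subtitles_recommended = ifelse(structured, missing == 0L, NA),
    item6_missing_headings = missing,
    item7_search_date = sample(c("month_and_year", "year_only", "none"), n,
                               replace = TRUE),
    item8_strategy = rand_list(c("MEDLINE", "EMBASE", "boolean_syntax"), 0.3),
    item9_population = ifelse(empty, NA, runif(n) < 0.5),
    item10_studies_stated = ifelse(empty, NA, runif(n) < 0.5),
    item11_participants_stated = ifelse(empty, NA, runif(n) < 0.5),
    item12_stats = rand_list(c("ci", "smd", "odds_ratio"), 0.3),
    item13_quality = ifelse(empty, NA, q13),
    item14_grade = ifelse(empty, NA, q14)
  )
  tib$item12_stats[empty] <- list(NULL)
  tib
}

# move one item of one assessment row toward adherence; returns the row
improve_one_item <- function(row, item) {
  switch(item,
    item1 = { row$item1_title_same <- FALSE },
    item2 = { row$item2_word_count <- 550L },
    item3 = { row$item3_jargon <- list(character(0)) },
    item4 = {
      row$item4_structured <- TRUE
      if (is.na(row$item6_missing_headings)) {
        row$item6_missing_headings <- 5L
        row$item5_subtitles_recommended <- FALSE
      }
    },
    item5 = if (isTRUE(row$item4_structured)) {
      row$item5_subtitles_recommended <- TRUE
      row$item6_missing_headings <- 0L
    },
    item6 = if (isTRUE(row$item4_structured) &&
                row$item6_missing_headings > 0L) {
      row$item6_missing_headings <- row$item6_missing_headings - 1L
      row$item5_subtitles_recommended <- row$item6_missing_headings == 0L
    },
    item7 = { row$item7_search_date <- "month_and_year" },
    item8 = { row$item8_strategy <- list(character(0)) },
    item9 = if (!row$is_empty_review) { row$item9_population <- TRUE },
    item10 = if (!row$is_empty_review) { row$item10_studies_stated <- TRUE },
    item11 = if (!row$is_empty_review) {
      row$item11_participants_stated <- TRUE
    },
    item12 = if (!row$is_empty_review) { row$item12_stats <- list(character(0)) },
    item13 = if (!row$is_empty_review) { row$item13_quality <- TRUE },
    item14 = if (!row$is_empty_review) {
      row$item14_grade <- TRUE
      row$item13_quality <- TRUE
    }
  )
  row
}

tiny_corpus <- function() {
  tibble::tibble(
    doc_id = c("A1", "A2", "A3"),
    review_title = c("Honey for cough", "Massage for back pain",
                     "Antibiotics for sore throat"),
    pls_title = c("Does honey help cough?", "Massage for back pain",
                  "Do antibiotics help sore throat?"),
    body = c(
      "We included 12 studies with 480 participants. The quality of the evidence was moderate.",
      "## Background\nBack pain is common.\n## Key results\nMassage helped a little.",
      "We found no studies that met the inclusion criteria."
    ),
    pub_month = c(4L, 9L, NA),
    pub_year = c(2013L, 2014L, 2014L),
    review_group = c("G1", "G1", "G2"),
    is_empty_review = c(FALSE, FALSE, TRUE)
  )
}
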