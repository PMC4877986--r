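lex <- pls_lexicons()

test_that("word counting is whitespace-token based and ignores heading markers", {
  expect_equal(count_words(""), 0L)
  expect_equal(count_words("Antibiotics reduce sore throat duration."), 5L)
  expect_equal(count_words("## Key results\nPain fell."), 4L)
})

test_that("title comparison normalizes case, whitespace and terminal punctuation", {
  expect_true(title_identical("Antibiotics for sore throat",
                              "Antibiotics for sore throat"))
  expect_false(title_identical("Antibiotics for sore throat",
                               "Do antibiotics help sore throat?"))
  expect_true(title_identical("Antibiotics  for sore throat.",
                              "antibiotics for sore throat"))
  expect_error(title_identical("", "x"), "non-empty")
})

test_that("jargon matching is whole-word, case-insensitive, with plural stemming", {
  expect_equal(nrow(find_jargon("We looked at pain relief.", lex)), 0)
  hits <- find_jargon("The main outcome was pain; efficacy was high.", lex)
  expect_setequal(hits$term, c("outcome", "efficacy"))
  stemmed <- find_jargon("Outcomes were measured", lex, stemming = TRUE)
  expect_equal(stemmed$term, "outcome")
  expect_equal(nrow(find_jargon("Outcomes were measured", lex,
                                stemming = FALSE)), 0)
  # substring of a longer word must not fire
  expect_equal(nrow(find_jargon("The outcomes-based framework", lex,
                                stemming = FALSE)), 0)
})

test_that("ambiguous terms live in their own tier, reported only on request", {
  body <- "A local practice gave the control treatment; the outcome was good."
  default <- find_jargon(body, lex)
  expect_equal(default$term, "outcome")
  both <- find_jargon(body, lex, include_ambiguous = TRUE)
  expect_setequal(both$term[both$tier == "ambiguous"],
                  c("local", "practice", "control"))
  expect_equal(both$term[both$tier == "jargon"], "outcome")
})

test_that("structure detection finds headings and normalizes variants", {
  full <- paste("## Review question\nQ.", "## Background\nB.",
                "## Study characteristics\nS.", "## Key results\nK.",
                "## Quality of evidence\nE.", sep = "\n")
  res <- detect_structure(full, lex)
  expect_true(res$structured)
  expect_setequal(res$matched[[1]], lex$recommended_headings)
  expect_equal(res$missing_count, 0L)

  narrative <- detect_structure("Just prose. No headings here.", lex)
  expect_false(narrative$structured)
  expect_true(is.na(narrative$missing_count))

  partial <- detect_structure(
    "## Background\nB.\n## Key results\nK.\n## Conclusions\nC.", lex)
  expect_true(partial$structured)
  expect_setequal(partial$matched[[1]], c("Background", "Key results"))
  expect_equal(partial$missing_count, 3L)

  variants <- detect_structure(
    "## Review questions:\nQ.\n## QUALITY OF THE EVIDENCE\nE.", lex)
  expect_setequal(variants$matched[[1]],
                  c("Review question", "Quality of evidence"))
})

test_that("unmarked heading heuristic is available behind its flag", {
  body <- "Key results\nPain improved with treatment."
  expect_false(detect_structure(body, lex)$structured)
  res <- detect_structure(body, lex, heading_heuristic = TRUE)
  expect_true(res$structured)
  expect_equal(res$matched[[1]], "Key results")
})

test_that("search-date tiers require a cue in the same sentence", {
  expect_equal(detect_search_date("The evidence is current to June 2014.")$tier,
               "month_and_year")
  expect_equal(detect_search_date("We searched databases in 2013.")$tier,
               "year_only")
  expect_equal(detect_search_date("We searched several databases.")$tier,
               "none")
  # a year outside any search sentence does not count
  two <- "The largest trial was published in 2010. We searched widely."
  expect_equal(detect_search_date(two)$tier, "none")
  # the month+year tier outranks year-only when both occur
  both <- "We searched in 2013. The evidence is current to June 2014."
  expect_equal(detect_search_date(both)$tier, "month_and_year")
})

test_that("strategy leaks: database names and search syntax, not generic words", {
  hits <- find_strategy_details("We searched MEDLINE and EMBASE.", lex)
  expect_setequal(hits$pattern, c("MEDLINE", "EMBASE"))
  expect_equal(nrow(find_strategy_details("We searched medical databases.",
                                          lex)), 0)
  bool <- find_strategy_details("using the terms ('pain' AND 'child')", lex)
  expect_true("boolean_syntax" %in% bool$pattern)
  expect_true("mesh" %in%
                find_strategy_details("MeSH headings were combined.",
                                      lex)$pattern)
})

test_that("population details need a qualified population noun", {
  expect_true(detect_population_details("adults aged over 65 with diabetes"))
  expect_true(detect_population_details("We studied pregnant women."))
  expect_false(detect_population_details(
    "This review assessed one drug versus another."))
  expect_false(detect_population_details(
    "People were generally satisfied."))
})

test_that("count statements parse numerals, separators and spelled numbers", {
  body <- "We included 12 studies (2,317 participants)."
  st <- detect_count_statement(body, "studies")
  expect_true(st$stated)
  expect_equal(st$value, 12L)
  pt <- detect_count_statement(body, "participants")
  expect_true(pt$stated)
  expect_equal(pt$value, 2317L)

  sp <- detect_count_statement("Twelve trials met the criteria.", "studies")
  expect_equal(sp$value, 12L)

  none <- detect_count_statement("Several studies were included.", "studies")
  expect_false(none$stated)

  zero <- detect_count_statement("We found no trials.", "studies")
  expect_true(zero$stated)
  expect_equal(zero$value, 0L)
  off <- detect_count_statement("We found no trials.", "studies",
                                count_none_as_stated = FALSE)
  expect_false(off$stated)
})

test_that("statistical notation is flagged unless explained within the window", {
  hit <- find_unexplained_stats(
    "pain decreased (SMD -0.41, 95 % CI -0.62 to -0.21)", lex)
  expect_setequal(hit$pattern, c("smd", "ci"))

  expect_equal(nrow(find_unexplained_stats(
    "about 3 more people in 100 improved", lex)), 0)

  suppressed <- find_unexplained_stats(
    "RR 0.80; this means 20 % fewer events", lex)
  expect_equal(nrow(suppressed), 0)

  # a cue far beyond the window no longer explains the statistic
  far <- paste("RR 0.80 was found for the main comparison across the",
               "included trials and follow-up periods of the review;",
               "this means little on its own.")
  expect_true("risk_ratio" %in% find_unexplained_stats(far, lex,
                                                       window = 3)$pattern)

  # a bare mention without a value is not complex statistical data
  expect_equal(nrow(find_unexplained_stats(
    "We planned to report risk ratios where possible.", lex)), 0)
})

test_that("quality statements and GRADE are detected with the right case rules", {
  q <- detect_quality_statement("The quality of the evidence was low.", lex)
  expect_true(q$quality_addressed)
  expect_false(q$grade_mentioned)

  g <- detect_quality_statement("We rated certainty using GRADE.", lex)
  expect_true(g$quality_addressed)
  expect_true(g$grade_mentioned)

  essays <- detect_quality_statement("We graded the essays", lex)
  expect_false(essays$quality_addressed)
  expect_false(essays$grade_mentioned)

  # a bare recommended heading is structure, not content
  heading_only <- detect_quality_statement(
    "## Quality of evidence\nNothing was said here.", lex)
  expect_false(heading_only$quality_addressed)
})

test_that("assess() enforces the applicability rules and is deterministic", {
  fx <- make_fixture("empty_review_basic")
  a <- assess_pls(fx$document)
  expect_true(is.na(a$item9_population))
  expect_true(is.na(a$item13_quality))
  expect_null(a$item12_stats[[1]])

  gen <- generate_corpus(generator_config(n_docs = 30, seed = 21,
                                          empty_fraction = 0.3))
  a1 <- assess_corpus(gen$corpus)
  a2 <- assess_corpus(gen$corpus)
  expect_equal(a1, a2)

  # applicability closure on every emitted assessment
  expect_silent(plscore:::check_applicability(a1))
})

test_that("adding jargon never shrinks matches; removing a heading never adds one", {
  base <- "We compared two treatments. The outcome was pain."
  more <- paste(base, "The efficacy was high.")
  expect_true(all(find_jargon(base, lex)$term %in% find_jargon(more, lex)$term))

  full <- paste("## Review question\nQ.", "## Background\nB.",
                "## Key results\nK.", sep = "\n")
  less <- "## Review question\nQ.\n## Background\nB.\nK."
  m_full <- detect_structure(full, lex)$matched[[1]]
  m_less <- detect_structure(less, lex)$matched[[1]]
  expect_true(all(m_less %in% m_full))
  expect_lte(length(m_less), length(m_full))
})

test_that("the bundled lexicon file reproduces the in-code defaults", {
  path <- system.file("extdata", "default_lexicons.txt", package = "plscore")
  expect_true(file.exists(path))
  expect_equal(read_lexicons(path), pls_lexicons())

  # overriding one section keeps the rest at their defaults
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("[jargon_terms]", "meta-analysis", "heterogeneity"), tmp)
  lex <- read_lexicons(tmp)
  expect_equal(lex$jargon_terms, c("meta-analysis", "heterogeneity"))
  expect_equal(lex$recommended_headings, pls_lexicons()$recommended_headings)
  hit <- find_jargon("We saw high heterogeneity.", lex)
  expect_equal(hit$term, "heterogeneity")
})
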