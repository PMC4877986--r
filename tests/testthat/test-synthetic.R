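test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- generator_config(n_docs = 25, seed = 101)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_generate(cfg, d1)
  run_generate(cfg, d2)
  for (f in c("corpus.jsonl", "labels.jsonl")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  other <- generate_corpus(generator_config(n_docs = 25, seed = 102))
  expect_false(identical(other$corpus$body,
                         generate_corpus(cfg)$corpus$body))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(55)
  before <- runif(3)
  set.seed(55)
  invisible(generate_corpus(generator_config(n_docs = 3, seed = 9)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("clean-mode labels are recovered exactly by the detectors", {
  for (seed in c(2, 31, 77)) {
    gen <- generate_corpus(generator_config(n_docs = 60, seed = seed))
    cmp <- compare_assessments(assess_corpus(gen$corpus), gen$labels)
    expect_equal(min(cmp$agreement), 1,
                 info = paste("seed", seed))
  }
})

test_that("empirical item rates converge to the configured rates", {
  flat_groups <- tibble::tibble(label = c("A", "B"), offset = c(0, 0))
  cfg <- generator_config(n_docs = 1000, seed = 19, groups = flat_groups,
                          trend_slope = 0)
  gen <- generate_corpus(cfg)
  lab <- gen$labels

  rate_of <- function(x) mean(x, na.rm = TRUE)
  checks <- list(
    c(rate_of(!lab$item1_title_same), cfg$rates[["item1"]], 1000),
    c(rate_of(lengths(lab$item3_jargon) == 0), cfg$rates[["item3"]], 1000),
    c(rate_of(lab$item4_structured), cfg$rates[["item4"]], 1000),
    c(rate_of(lengths(lab$item8_strategy) == 0), cfg$rates[["item8"]], 1000),
    c(rate_of(lab$item9_population), cfg$rates[["item9"]],
      sum(!lab$is_empty_review)),
    c(rate_of(lab$item13_quality), cfg$rates[["item13"]],
      sum(!lab$is_empty_review)),
    c(mean(lab$is_empty_review), cfg$empty_fraction, 1000),
    c(rate_of(lab$item7_search_date == "month_and_year"),
      cfg$item7_probs[["month_and_year"]], 1000)
  )
  for (ch in checks) {
    se <- sqrt(ch[2] * (1 - ch[2]) / ch[3])
    expect_lt(abs(ch[1] - ch[2]), 3 * se + 1e-9)
  }

  # word-count distribution: mean within 2 standard errors of the target
  ws <- word_stats(gen$corpus)
  expect_lt(abs(ws$mean - cfg$word_mean), 2 * cfg$word_sd / sqrt(1000) + 2)
  expect_gte(ws$min, cfg$word_min - 5)
})

test_that("a configured adherence trend is recovered by the regression", {
  mid_rates <- c(item1 = 0.5, item3 = 0.5, item4 = 0.4, item8 = 0.6,
                 item9 = 0.5, item10 = 0.5, item11 = 0.5, item12 = 0.6,
                 item13 = 0.5, item14 = 0.05)
  slope_prob <- 0.008
  cfg <- generator_config(
    n_docs = 800, seed = 47, empty_fraction = 0, rates = mid_rates,
    groups = tibble::tibble(label = "G", offset = 0),
    trend_slope = slope_prob
  )
  gen <- generate_corpus(cfg)
  scores <- score_assessments(gen$labels)
  scores$month_index <- month_index(gen$corpus$pub_year,
                                    gen$corpus$pub_month)
  tr <- trend_analysis(scores)
  # 8 unit-weight items shift with time, so the expected percentage slope is
  # slope_prob * 8 / 19 * 100
  expected <- slope_prob * 8 / 19 * 100
  td <- tidy(tr)
  est <- td$estimate[td$term == "month_index"]
  se <- td$std.error[td$term == "month_index"]
  expect_lt(abs(est - expected), qt(0.975, tr$n_used - 2) * se)
  expect_gt(tr$pearson_r, 0)
  expect_lt(tr$slope_p, 0.001)
})

test_that("degenerate configurations are rejected up front", {
  expect_error(generator_config(n_docs = 0), "n_docs")
  expect_error(generator_config(n_docs = 5, empty_fraction = 1.4), "\\[0, 1\\]")
  expect_error(generator_config(n_docs = 5, month_range = integer(0)),
               "month_range")
  expect_error(generator_config(n_docs = 5, word_mean = 40, word_min = 46),
               "word_mean")
  expect_error(generator_config(n_docs = 5,
                                rates = c(item13 = 0.1, item14 = 0.5)),
               "item14")
})

test_that("rate extremes force the score ceiling and floor", {
  perfect <- generator_config(
    n_docs = 12, empty_fraction = 0,
    rates = c(item1 = 1, item3 = 1, item4 = 1, item8 = 1, item9 = 1,
              item10 = 1, item11 = 1, item12 = 1, item13 = 1, item14 = 1),
    item6_dist = c(1, 0, 0, 0, 0, 0),
    item7_probs = c(month_and_year = 1, year_only = 0, none = 0),
    word_mean = 550, word_sd = 25, word_min = 450,
    groups = tibble::tibble(label = "G", offset = 0), trend_slope = 0,
    seed = 3
  )
  gp <- generate_corpus(perfect)
  sp <- score_assessments(assess_corpus(gp$corpus) |>
                            dplyr::select(-item3_ambiguous))
  expect_true(all(sp$points == 19))
  expect_true(all(sp$percentage == 100))

  worst <- generator_config(
    n_docs = 12, empty_fraction = 0,
    rates = c(item1 = 0, item3 = 0, item4 = 0, item8 = 0, item9 = 0,
              item10 = 0, item11 = 0, item12 = 0, item13 = 0, item14 = 0),
    item7_probs = c(month_and_year = 0, year_only = 0, none = 1),
    word_mean = 150, word_sd = 20, word_min = 46,
    groups = tibble::tibble(label = "G", offset = 0), trend_slope = 0,
    seed = 4
  )
  gw <- generate_corpus(worst)
  sw <- score_assessments(assess_corpus(gw$corpus) |>
                            dplyr::select(-item3_ambiguous))
  expect_true(all(sw$points == 0))
})

test_that("empty_fraction = 1 yields only empty reviews with items 9-14 not applicable", {
  gen <- generate_corpus(generator_config(n_docs = 10, empty_fraction = 1,
                                          seed = 6))
  expect_true(all(gen$corpus$is_empty_review))
  expect_true(all(is.na(gen$labels$item9_population)))
  expect_true(all(vapply(gen$labels$item12_stats, is.null, logical(1))))
  s <- score_assessments(gen$labels)
  expect_true(all(s$max_points == 13L))
})

test_that("hand-authored fixtures match their frozen expectations", {
  for (name in c("minimal_three_sentence", "empty_review_basic",
                 "heading_variants", "narrative_perfect")) {
    fx <- make_fixture(name)
    a <- assess_pls(fx$document) |> dplyr::select(-item3_ambiguous)
    cmp <- compare_assessments(a, fx$assessment)
    expect_equal(min(cmp$agreement), 1, info = name)
    got <- score_assessments(a)
    expect_equal(got$points, fx$result$points, info = name)
    expect_equal(got$band, fx$result$band, info = name)
  }
  fx <- make_fixture("minimal_three_sentence")
  expect_equal(fx$assessment$item2_word_count, 46L)
  expect_equal(make_fixture("empty_review_basic")$result$max_points, 13L)
  expect_equal(make_fixture("heading_variants")$assessment$item6_missing_headings,
               0L)
})
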