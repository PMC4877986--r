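test_that("word statistics match hand-computed values", {
  one <- tiny_corpus()[1, ]
  one$body <- paste(rep("w", 300), collapse = " ")
  ws <- word_stats(one)
  expect_equal(ws$mean, 300)
  expect_equal(ws$median, 300)
  expect_equal(c(ws$min, ws$max), c(300, 300))

  three <- tiny_corpus()
  three$body <- vapply(c(100, 200, 600),
                       function(n) paste(rep("w", n), collapse = " "), "")
  ws3 <- word_stats(three)
  expect_equal(ws3$mean, 300)
  expect_equal(ws3$median, 200)
})

test_that("the item table uses the four published denominators", {
  corp <- tiny_corpus()  # 3 docs: one structured (non-conforming), one empty
  rep <- corpus_report(corp)
  it <- rep$item_adherence
  expect_equal(rep$counts$n_total, 3L)
  expect_equal(rep$counts$n_empty, 1L)
  expect_equal(rep$counts$n_structured, 1L)
  expect_equal(rep$counts$n_structured_nonconforming, 1L)

  denom_of <- function(k) unique(it$denominator[it$item == k])
  for (k in c(1, 2, 3, 4, 7, 8)) expect_equal(denom_of(k), 3L)
  for (k in 9:14) expect_equal(denom_of(k), 2L)
  expect_equal(denom_of(5), 1L)
  expect_equal(denom_of(6), 1L)

  # item-6 distribution rows count the non-conforming structured PLSs
  expect_equal(sum(it$count[it$item == 6]),
               rep$counts$n_structured_nonconforming)
})

test_that("a single fully adherent document reports 100 % everywhere applicable", {
  gen <- generate_corpus(generator_config(
    n_docs = 1, empty_fraction = 0,
    rates = c(item1 = 1, item3 = 1, item4 = 1, item8 = 1, item9 = 1,
              item10 = 1, item11 = 1, item12 = 1, item13 = 1, item14 = 1),
    item6_dist = c(1, 0, 0, 0, 0, 0),
    item7_probs = c(month_and_year = 1, year_only = 0, none = 0),
    word_mean = 550, word_sd = 25, word_min = 450,
    groups = tibble::tibble(label = "G", offset = 0), trend_slope = 0,
    seed = 2
  ))
  rep <- corpus_report(gen$corpus)
  it <- rep$item_adherence
  applicable <- it[it$denominator > 0 & !(it$measure %in% paste(1:5, "missing")) &
                     it$measure != "Search date: year only", ]
  expect_true(all(applicable$percent == 100))
  bands <- rep$band_counts
  expect_equal(bands$count[bands$context == "included_studies" &
                             bands$band == "76-100"], 1L)
})

test_that("band counts are conserved within each context", {
  gen <- generate_corpus(generator_config(n_docs = 150, seed = 17))
  rep <- corpus_report(gen$corpus)
  bands <- rep$band_counts
  sums <- tapply(bands$count, bands$context, sum)
  expect_equal(unname(sums[["empty_review"]]),
               as.integer(rep$counts$n_empty))
  expect_equal(unname(sums[["included_studies"]]),
               as.integer(rep$counts$n_total - rep$counts$n_empty))
})

test_that("group means weighted by group size recover the overall mean", {
  gen <- generate_corpus(generator_config(n_docs = 120, seed = 23))
  rep <- corpus_report(gen$corpus)
  g <- rep$group_summaries
  weighted <- sum(g$mean_pct * g$n_pls) / sum(g$n_pls)
  expect_equal(weighted, mean(rep$scores$percentage))
})

test_that("an exact linear adherence trend is recovered exactly", {
  d <- tibble::tibble(month_index = 0:22, percentage = 50 + 1.0 * (0:22))
  tr <- suppressWarnings(trend_analysis(d))  # lm warns on a perfect fit
  expect_equal(tr$slope, 1.0)
  expect_equal(tr$pearson_r, 1.0)
  expect_equal(tr$n_used, 23L)
  td <- suppressWarnings(tidy(tr))
  expect_equal(td$estimate[td$term == "month_index"], 1.0)
})

test_that("degenerate trend inputs are flagged, not silently fitted", {
  const <- tibble::tibble(month_index = 0:10, percentage = rep(60, 11))
  tr <- suppressWarnings(trend_analysis(const))
  expect_equal(tr$slope, 0)
  expect_true(is.na(tr$pearson_r))
  expect_true(tr$zero_variance)

  same_month <- tibble::tibble(month_index = rep(4, 10),
                               percentage = runif(10, 40, 80))
  expect_error(trend_analysis(same_month), "Degenerate")
  expect_error(trend_analysis(tibble::tibble(month_index = 1:2,
                                             percentage = c(10, 20))),
               "at least 3")
})

test_that("shuffling the time index gives approximately uniform slope p-values", {
  set.seed(31)
  n <- 150
  d <- tibble::tibble(month_index = sample(0:22, n, replace = TRUE),
                      percentage = rnorm(n, 57, 12))
  ps <- replicate(300, {
    shuffled <- d
    shuffled$month_index <- sample(shuffled$month_index)
    trend_analysis(shuffled)$slope_p
  })
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("tidy/glance/autoplot methods expose the report and trend", {
  gen <- generate_corpus(generator_config(n_docs = 40, seed = 29))
  rep <- corpus_report(gen$corpus)
  expect_s3_class(tidy(rep), "tbl_df")
  gl <- glance(rep)
  expect_true(all(c("n_total", "mean_pct_included", "pearson_r") %in%
                    names(gl)))
  expect_s3_class(autoplot(rep), "ggplot")
  if (!is.null(rep$trend)) {
    expect_s3_class(autoplot(rep$trend), "ggplot")
    expect_true(abs(rep$trend$pearson_r) <= 1)
  }
})
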