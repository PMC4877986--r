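#' Word-count statistics over a corpus
#'
#' @param corpus A corpus tibble.
#' @return One-row tibble: `n`, `mean`, `median`, `min`, `max` of
#'   [count_words()] over the bodies.
#' @examples
#' gen <- generate_corpus(generator_config(n_docs = 20, seed = 1))
#' word_stats(gen$corpus)
#' @export
word_stats <- function(corpus) {
  corpus <- pls_corpus(corpus)
  if (nrow(corpus) == 0) {
    stop("Cannot summarise an empty corpus.", call. = FALSE)
  }
  wc <- map_int(corpus$body, count_words)
  tibble(n = length(wc), mean = mean(wc), median = median(wc),
         min = min(wc), max = max(wc))
}

#' Adherence-over-time trend analysis
#'
#' Pearson correlation and ordinary least-squares regression of per-document
#' adherence percentage on publication time (months since the origin month;
#' see [month_index()]). The slope's p-value is the two-sided t-test for a
#' zero slope. Documents without a time index are dropped.
#'
#' @param scores A tibble with columns `percentage` and `month_index`
#'   (e.g. [score_assessments()] output joined with [add_month_index()]
#'   metadata).
#' @return An object of class `pls_trend` with fields `pearson_r`, `slope`
#'   (adherence-percentage points per month), `intercept`, `slope_p`,
#'   `n_used`, `zero_variance` and the underlying `lm` fit. Supports
#'   [tidy()], [glance()], [autoplot()].
#' @examples
#' d <- tibble::tibble(month_index = 0:22, percentage = 50 + 1.0 * (0:22))
#' glance(trend_analysis(d))
#' @export
trend_analysis <- function(scores) {
  if (!all(c("percentage", "month_index") %in% names(scores))) {
    stop("`scores` needs columns `percentage` and `month_index`.",
         call. = FALSE)
  }
  d <- scores[complete.cases(scores[, c("percentage", "month_index")]), ]
  d <- d[is.finite(d$percentage) & is.finite(d$month_index), ]
  if (nrow(d) < 3) {
    stop("Trend analysis needs at least 3 documents with a time index.",
         call. = FALSE)
  }
  if (var(d$month_index) == 0) {
    stop("Degenerate design: all publication months identical.",
         call. = FALSE)
  }
  zero_var <- var(d$percentage) == 0
  r <- if (zero_var) NA_real_ else cor(d$month_index, d$percentage)
  fit <- lm(percentage ~ month_index, data = d)
  ct <- summary(fit)$coefficients
  slope_p <- if (zero_var) NA_real_ else ct["month_index", "Pr(>|t|)"]
  structure(
    list(
      pearson_r = r,
      slope = unname(coef(fit)["month_index"]),
      intercept = unname(coef(fit)["(Intercept)"]),
      slope_p = slope_p,
      n_used = nrow(d),
      zero_variance = zero_var,
      model = fit,
      data = as_tibble(d[, c("month_index", "percentage")])
    ),
    class = "pls_trend"
  )
}

#' @export
print.pls_trend <- function(x, ...) {
  cat("<pls_trend> adherence vs publication month (n =", x$n_used, ")\n")
  cat(sprintf("  Pearson r: %s\n",
              ifelse(is.na(x$pearson_r), "undefined (zero variance)",
                     sprintf("%.3f", x$pearson_r))))
  cat(sprintf("  slope: %.4f %%/month (p = %s)\n", x$slope,
              format.pval(x$slope_p, digits = 3)))
  invisible(x)
}

#' @rdname trend_analysis
#' @param x A `pls_trend` object.
#' @param ... Unused.
#' @method tidy pls_trend
#' @export
tidy.pls_trend <- function(x, ...) {
  ct <- summary(x$model)$coefficients
  tibble(
    term = rownames(ct),
    estimate = unname(ct[, "Estimate"]),
    std.error = unname(ct[, "Std. Error"]),
    statistic = unname(ct[, "t value"]),
    p.value = unname(ct[, "Pr(>|t|)"])
  )
}

#' @rdname trend_analysis
#' @method glance pls_trend
#' @export
glance.pls_trend <- function(x, ...) {
  tibble(pearson_r = x$pearson_r, slope = x$slope, intercept = x$intercept,
         slope_p = x$slope_p, n_used = x$n_used,
         zero_variance = x$zero_variance)
}

#' @rdname trend_analysis
#' @param object A `pls_trend` object.
#' @method autoplot pls_trend
#' @export
autoplot.pls_trend <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$month_index,
                               y = .data$percentage)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "firebrick") +
    ggplot2::labs(x = "Months since origin month",
                  y = "Adherence (%)",
                  title = "PLS adherence over publication time") +
    ggplot2::theme_minimal()
}

item_measure_labels <- function() {
  tibble(
    item = c(1L, 2L, 3L, 4L, 5L, 8L, 9L, 10L, 11L, 12L, 13L, 14L),
    measure = c(
      "Title restated in plain language",
      "Word count within recommended range",
      "Technical terms and jargon absent",
      "PLS structured",
      "If structured, subtitles as recommended",
      "Details of search strategy absent",
      "Population details provided",
      "Number of studies indicated",
      "Number of participants indicated",
      "Complex unexplained statistical data absent",
      "Quality of the studies addressed",
      "GRADE system mentioned"
    )
  )
}

#' Corpus-level adherence report
#'
#' Aggregates per-document assessments and scores into the corpus summary:
#' the per-item adherence table with its four denominators (items 1-4 and
#' 7-8 over all documents; items 9-14 over non-empty reviews; item 5 over
#' structured PLSs; item 6 over structured-but-not-fully-recommended PLSs),
#' the adherence-band distributions for the two contexts, word-count
#' statistics, per-review-group mean adherence, and — when enough documents
#' carry a publication month — the adherence-over-time trend.
#'
#' @param corpus A corpus tibble.
#' @param assessments Optional precomputed [assess_corpus()] output.
#' @param scores Optional precomputed [score_assessments()] output.
#' @param lexicons,scheme Used when assessments/scores must be computed.
#' @param ... Passed to [assess_corpus()] when assessments are computed here.
#' @return An object of class `pls_report`: a list with `counts`,
#'   `item_adherence`, `band_counts`, `word_stats`, `group_summaries`,
#'   `trend` (a `pls_trend` or `NULL`), and `overall` (mean adherence
#'   percentage per context). Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' gen <- generate_corpus(generator_config(n_docs = 30, seed = 1))
#' rep <- corpus_report(gen$corpus)
#' glance(rep)
#' @export
corpus_report <- function(corpus, assessments = NULL, scores = NULL,
                          lexicons = pls_lexicons(),
                          scheme = default_scheme(), ...) {
  corpus <- pls_corpus(corpus)
  if (is.null(assessments)) {
    assessments <- assess_corpus(corpus, lexicons, ...)
  }
  if (!identical(sort(assessments$doc_id), sort(corpus$doc_id))) {
    stop("Assessments and corpus cover different doc_ids.", call. = FALSE)
  }
  if (is.null(scores)) {
    scores <- score_assessments(assessments, scheme)
  }
  if (!identical(sort(scores$doc_id), sort(corpus$doc_id))) {
    stop("Scores and corpus cover different doc_ids.", call. = FALSE)
  }
  a <- assessments[match(corpus$doc_id, assessments$doc_id), ]
  s <- scores[match(corpus$doc_id, scores$doc_id), ]

  n_total <- nrow(corpus)
  n_empty <- sum(corpus$is_empty_review)
  n_nonempty <- n_total - n_empty
  structured <- !is.na(a$item4_structured) & a$item4_structured
  n_structured <- sum(structured)
  nonconf <- structured & !is.na(a$item6_missing_headings) &
    a$item6_missing_headings > 0L
  n_nonconf <- sum(nonconf)

  none_found <- function(col) map_lgl(col, function(v) length(v) == 0)
  adhering <- list(
    `1` = sum(!a$item1_title_same),
    `2` = sum(a$item2_word_count >= scheme$word_range[1] &
                a$item2_word_count <= scheme$word_range[2]),
    `3` = sum(none_found(a$item3_jargon)),
    `4` = sum(structured),
    `5` = sum(structured & a$item5_subtitles_recommended %in% TRUE),
    `8` = sum(none_found(a$item8_strategy)),
    `9` = sum(a$item9_population %in% TRUE),
    `10` = sum(a$item10_studies_stated %in% TRUE),
    `11` = sum(a$item11_participants_stated %in% TRUE),
    `12` = sum(!a$is_empty_review & none_found(a$item12_stats)),
    `13` = sum(a$item13_quality %in% TRUE),
    `14` = sum(a$item14_grade %in% TRUE)
  )
  denom <- c(`1` = n_total, `2` = n_total, `3` = n_total, `4` = n_total,
             `5` = n_structured, `8` = n_total, `9` = n_nonempty,
             `10` = n_nonempty, `11` = n_nonempty, `12` = n_nonempty,
             `13` = n_nonempty, `14` = n_nonempty)
  base <- item_measure_labels()
  base$count <- unname(unlist(adhering)[as.character(base$item)])
  base$denominator <- unname(denom[as.character(base$item)])

  item6_rows <- tibble(
    item = 6L,
    measure = paste(1:5, "missing"),
    count = map_int(1:5, function(k) {
      sum(nonconf & a$item6_missing_headings == k)
    }),
    denominator = n_nonconf
  )
  item7_rows <- tibble(
    item = 7L,
    measure = c("Search date: month and year", "Search date: year only"),
    count = c(sum(a$item7_search_date == "month_and_year"),
              sum(a$item7_search_date == "year_only")),
    denominator = n_total
  )
  item_adherence <- bind_rows(base, item6_rows, item7_rows)
  item_adherence <- arrange(item_adherence, .data$item)
  item_adherence$percent <- ifelse(
    item_adherence$denominator > 0,
    item_adherence$count / item_adherence$denominator * 100, NA_real_)
  item_adherence$pct_display <- round_half_up(item_adherence$percent)

  band_levels <- c("0-25", "26-50", "51-75", "76-100")
  band_counts <- bind_rows(map(c(FALSE, TRUE), function(empty) {
    sub <- s[s$is_empty_review == empty, ]
    tibble(
      context = if (empty) "empty_review" else "included_studies",
      band = band_levels,
      count = map_int(band_levels, function(b) sum(sub$band == b)),
      n_context = nrow(sub)
    )
  }))
  band_counts$percent <- ifelse(band_counts$n_context > 0,
                                band_counts$count / band_counts$n_context * 100,
                                NA_real_)

  by_group <- corpus[, c("doc_id", "review_group")]
  gs <- dplyr::left_join(s, by_group, by = "doc_id")
  group_summaries <- summarise(
    group_by(gs, .data$review_group),
    n_pls = dplyr::n(),
    mean_points = mean(.data$points),
    mean_pct = mean(.data$percentage),
    .groups = "drop"
  )

  with_time <- add_month_index(corpus)
  trend_input <- dplyr::left_join(
    s, with_time[, c("doc_id", "month_index")], by = "doc_id")
  trend <- NULL
  if (sum(complete.cases(trend_input[, c("percentage", "month_index")])) >= 3 &&
      length(unique(stats::na.omit(trend_input$month_index))) > 1) {
    trend <- trend_analysis(trend_input)
  }

  overall <- summarise(
    group_by(s, .data$is_empty_review),
    n = dplyr::n(),
    mean_points = mean(.data$points),
    mean_pct = mean(.data$percentage),
    .groups = "drop"
  )

  structure(
    list(
      counts = tibble(n_total = n_total, n_empty = n_empty,
                      n_structured = n_structured,
                      n_structured_nonconforming = n_nonconf),
      item_adherence = item_adherence,
      band_counts = band_counts,
      word_stats = word_stats(corpus),
      group_summaries = group_summaries,
      overall = overall,
      trend = trend,
      scores = s
    ),
    class = "pls_report"
  )
}

#' @export
print.pls_report <- function(x, ...) {
  cts <- x$counts
  cat("<pls_report>", cts$n_total, "PLS documents (", cts$n_empty,
      "empty reviews,", cts$n_structured, "structured )\n")
  nonempty <- x$overall[!x$overall$is_empty_review, ]
  if (nrow(nonempty) == 1) {
    cat(sprintf("  mean adherence (included studies): %.1f points = %.0f%%\n",
                nonempty$mean_points, nonempty$mean_pct))
  }
  emp <- x$overall[x$overall$is_empty_review, ]
  if (nrow(emp) == 1) {
    cat(sprintf("  mean adherence (empty reviews): %.1f points = %.0f%%\n",
                emp$mean_points, emp$mean_pct))
  }
  cat("  item adherence table:", nrow(x$item_adherence), "rows;",
      "use tidy() for the full table\n")
  if (!is.null(x$trend)) {
    cat(sprintf("  trend: slope %.3f %%/month, r = %.3f, p = %s\n",
                x$trend$slope, x$trend$pearson_r,
                format.pval(x$trend$slope_p, digits = 3)))
  }
  invisible(x)
}

#' @rdname corpus_report
#' @param x,object A `pls_report`.
#' @method tidy pls_report
#' @export
tidy.pls_report <- function(x, ...) {
  x$item_adherence
}

#' @rdname corpus_report
#' @method glance pls_report
#' @export
glance.pls_report <- function(x, ...) {
  nonempty <- x$overall[!x$overall$is_empty_review, ]
  emp <- x$overall[x$overall$is_empty_review, ]
  tibble(
    n_total = x$counts$n_total,
    n_empty = x$counts$n_empty,
    n_structured = x$counts$n_structured,
    mean_pct_included = if (nrow(nonempty)) nonempty$mean_pct else NA_real_,
    mean_pct_empty = if (nrow(emp)) emp$mean_pct else NA_real_,
    mean_words = x$word_stats$mean,
    pearson_r = if (!is.null(x$trend)) x$trend$pearson_r else NA_real_,
    trend_slope = if (!is.null(x$trend)) x$trend$slope else NA_real_,
    trend_p = if (!is.null(x$trend)) x$trend$slope_p else NA_real_
  )
}

#' @rdname corpus_report
#' @method autoplot pls_report
#' @export
autoplot.pls_report <- function(object, ...) {
  d <- object$item_adherence
  d <- d[!is.na(d$percent), ]
  d$label <- paste0(d$item, ": ", d$measure)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$label,
                                                     .data$percent),
                                  y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Adherence (%)",
                  title = "Per-item adherence") +
    ggplot2::theme_minimal()
}
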