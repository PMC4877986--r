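#' The default adherence scoring scheme
#'
#' Points per item, reproducing the published per-context maxima: a PLS of a
#' review with included studies can earn 0-19 points, the PLS of an empty
#' review 0-13 points (items 9-14 are not collected for empty reviews).
#'
#' Default point rules:
#' * items 1, 2, 3, 4, 5, 8 and 9-14: 1 point each (binary);
#' * items 1, 3, 8 and 12 are *reverse-scored* — the point is awarded when
#'   the measured element (identical title, jargon, search-strategy detail,
#'   unexplained statistics) is **absent**;
#' * item 2: the point requires a word count inside `word_range`
#'   (400-700 by default);
#' * item 6: graded, `5 - missing_headings` points (0-5); a narrative PLS
#'   earns 0 for items 4-6;
#' * item 7: tiered — month and year 2 points, year only 1, none 0.
#'
#' Not-applicable items contribute 0 points, and the maximum is fixed by
#' context (19 or 13), not reduced per document. The scheme is a plain list
#' and fully configurable; [verify_scheme()] re-derives the achievable maxima
#' by exhaustive enumeration so a modified scheme can be checked against its
#' declared constants, and [read_scheme()]/[write_scheme()] serialize it.
#'
#' @return An object of class `pls_scheme`.
#' @examples
#' sch <- default_scheme()
#' sch$max_nonempty  # 19
#' sch$max_empty     # 13
#' @export
default_scheme <- function() {
  new_pls_scheme(
    binary_points = c(item1 = 1, item2 = 1, item3 = 1, item4 = 1, item5 = 1,
                      item8 = 1, item9 = 1, item10 = 1, item11 = 1,
                      item12 = 1, item13 = 1, item14 = 1),
    item6_max = 5L,
    item7_tiers = c(month_and_year = 2, year_only = 1, none = 0),
    reverse_items = c(1L, 3L, 8L, 12L),
    word_range = c(400L, 700L),
    max_nonempty = 19L,
    max_empty = 13L
  )
}

#' @rdname default_scheme
#' @param binary_points Named numeric: points for each binary item
#'   (`item1`, `item2`, ..., excluding items 6 and 7).
#' @param item6_max Points for a fully recommended heading set; an
#'   assessment earns `item6_max - missing_headings` (floored at 0).
#' @param item7_tiers Named numeric: points per search-date tier.
#' @param reverse_items Integer vector of reverse-scored item numbers.
#' @param word_range Length-2 integer: inclusive adherent word-count range.
#' @param max_nonempty,max_empty Declared per-context maxima.
#' @export
new_pls_scheme <- function(binary_points, item6_max, item7_tiers,
                           reverse_items, word_range, max_nonempty,
                           max_empty) {
  needed <- paste0("item", c(1:5, 8:14))
  if (!setequal(names(binary_points), needed)) {
    stop("`binary_points` must name exactly items 1-5 and 8-14.",
         call. = FALSE)
  }
  if (!setequal(names(item7_tiers),
                c("month_and_year", "year_only", "none"))) {
    stop("`item7_tiers` must name the three search-date tiers.",
         call. = FALSE)
  }
  structure(
    list(
      binary_points = setNames(as.numeric(binary_points[needed]), needed),
      item6_max = as.integer(item6_max),
      item7_tiers = setNames(
        as.numeric(item7_tiers[c("month_and_year", "year_only", "none")]),
        c("month_and_year", "year_only", "none")),
      reverse_items = sort(as.integer(reverse_items)),
      word_range = as.integer(word_range),
      max_nonempty = as.integer(max_nonempty),
      max_empty = as.integer(max_empty),
      n_items = 14L
    ),
    class = "pls_scheme"
  )
}

#' @export
print.pls_scheme <- function(x, ...) {
  cat("<pls_scheme> 14 measured items\n")
  cat("  reverse-scored items:", paste(x$reverse_items, collapse = ", "),
      "\n")
  cat("  item 7 tiers:",
      paste(names(x$item7_tiers), x$item7_tiers, sep = "=", collapse = ", "),
      "\n")
  cat("  item 6: ", x$item6_max, " - missing headings\n", sep = "")
  cat("  word range (item 2): ", x$word_range[1], "-", x$word_range[2],
      "\n", sep = "")
  cat("  maxima: ", x$max_nonempty, " (included studies), ", x$max_empty,
      " (empty review)\n", sep = "")
  invisible(x)
}

#' @rdname read_pls_corpus
#' @description `read_scheme()`/`write_scheme()` serialize a scoring scheme
#'   as JSON.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "pls_scheme"))
  out <- unclass(scheme)
  # keep item names: named vectors serialize as JSON objects, not arrays
  out$binary_points <- as.list(out$binary_points)
  out$item7_tiers <- as.list(out$item7_tiers)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname default_scheme
#' @param path Path to a JSON scheme file written by `write_scheme()`.
#' @export
read_scheme <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_pls_scheme(
    binary_points = unlist(raw$binary_points),
    item6_max = raw$item6_max,
    item7_tiers = unlist(raw$item7_tiers),
    reverse_items = raw$reverse_items,
    word_range = raw$word_range,
    max_nonempty = raw$max_nonempty,
    max_empty = raw$max_empty
  )
}

# vectorized per-item points over an assessment tibble; returns a numeric
# matrix (documents x 14 items). NA / not-applicable values earn 0.
item_points_matrix <- function(a, scheme) {
  bp <- scheme$binary_points
  zero_na <- function(x) ifelse(is.na(x), 0, x)
  none_found <- function(col) map_lgl(col, function(v) length(v) == 0)
  pts <- cbind(
    item1 = bp["item1"] * zero_na(!a$item1_title_same),
    item2 = bp["item2"] * zero_na(a$item2_word_count >= scheme$word_range[1] &
                                    a$item2_word_count <= scheme$word_range[2]),
    item3 = bp["item3"] * none_found(a$item3_jargon),
    item4 = bp["item4"] * zero_na(a$item4_structured),
    item5 = bp["item5"] * zero_na(a$item5_subtitles_recommended),
    item6 = ifelse(is.na(a$item6_missing_headings), 0,
                   pmax(0, scheme$item6_max - a$item6_missing_headings)),
    item7 = unname(scheme$item7_tiers[a$item7_search_date]),
    item8 = bp["item8"] * none_found(a$item8_strategy),
    item9 = bp["item9"] * zero_na(a$item9_population),
    item10 = bp["item10"] * zero_na(a$item10_studies_stated),
    item11 = bp["item11"] * zero_na(a$item11_participants_stated),
    item12 = bp["item12"] *
      ifelse(a$is_empty_review, 0, none_found(a$item12_stats)),
    item13 = bp["item13"] * zero_na(a$item13_quality),
    item14 = bp["item14"] * zero_na(a$item14_grade)
  )
  # empty reviews: items 9-14 are out of scope regardless of the values
  pts[a$is_empty_review, c("item9", "item10", "item11", "item12", "item13",
                           "item14")] <- 0
  pts
}

check_applicability <- function(a) {
  empty <- a$is_empty_review
  na_list <- function(col) map_lgl(col, is.null)
  bad_914 <- empty & (!is.na(a$item9_population) |
                        !is.na(a$item10_studies_stated) |
                        !is.na(a$item11_participants_stated) |
                        !na_list(a$item12_stats) |
                        !is.na(a$item13_quality) | !is.na(a$item14_grade))
  bad_914_na <- !empty & (is.na(a$item9_population) |
                            is.na(a$item10_studies_stated) |
                            is.na(a$item11_participants_stated) |
                            na_list(a$item12_stats) |
                            is.na(a$item13_quality) | is.na(a$item14_grade))
  narr <- !is.na(a$item4_structured) & !a$item4_structured
  bad_56 <- narr & (!is.na(a$item5_subtitles_recommended) |
                      !is.na(a$item6_missing_headings))
  bad_56_na <- !narr & (is.na(a$item5_subtitles_recommended) |
                          is.na(a$item6_missing_headings))
  bad_grade <- !is.na(a$item14_grade) & a$item14_grade &
    !is.na(a$item13_quality) & !a$item13_quality
  bad <- bad_914 | bad_914_na | bad_56 | bad_56_na | bad_grade
  if (any(bad)) {
    stop("Applicability violation in assessment rows: ",
         paste(head(which(bad), 5), collapse = ", "),
         " (items 9-14 must be NA iff empty review; items 5-6 NA iff ",
         "narrative; GRADE implies quality addressed).", call. = FALSE)
  }
  invisible(TRUE)
}

round_half_up <- function(x) floor(x + 0.5)

adherence_band <- function(pct_display) {
  dplyr::case_when(
    pct_display <= 25 ~ "0-25",
    pct_display <= 50 ~ "26-50",
    pct_display <= 75 ~ "51-75",
    TRUE ~ "76-100"
  )
}

#' Score assessments under a scoring scheme
#'
#' Sums the per-item points of each assessment (not-applicable items
#' contribute 0) against the fixed per-context maximum — 19 points for a PLS
#' of a review with included studies, 13 for an empty review — and derives
#' the adherence percentage and band. Percentages are rounded half-up to
#' integers for display and banding (`0-25`, `26-50`, `51-75`, `76-100`); the
#' unrounded value is kept in `percentage`.
#'
#' @param assessments Output of [assess_corpus()] (or a label tibble with the
#'   same columns — labels and assessments score identically).
#' @param scheme A `pls_scheme`; defaults to [default_scheme()].
#' @param validate Check the applicability invariants first?
#' @return Tibble: `doc_id`, `is_empty_review`, `points`, `max_points`,
#'   `percentage`, `pct_display`, `band`.
#' @examples
#' gen <- generate_corpus(generator_config(n_docs = 5, seed = 1))
#' gen$corpus |> assess_corpus() |> score_assessments()
#' @export
score_assessments <- function(assessments, scheme = default_scheme(),
                              validate = TRUE) {
  if (validate) check_applicability(assessments)
  pts <- item_points_matrix(assessments, scheme)
  points <- unname(rowSums(pts))
  max_points <- ifelse(assessments$is_empty_review, scheme$max_empty,
                       scheme$max_nonempty)
  percentage <- points / max_points * 100
  pct_display <- round_half_up(percentage)
  tibble(
    doc_id = assessments$doc_id,
    is_empty_review = assessments$is_empty_review,
    points = points,
    max_points = max_points,
    percentage = percentage,
    pct_display = pct_display,
    band = adherence_band(pct_display)
  )
}

# every extreme-value combination of the 14 items for one context, as an
# assessment tibble. Structure options couple items 4-6; items 13-14 respect
# grade => quality.
enumerate_extremes <- function(scheme, empty) {
  structure_opts <- c(-1L, 0:5)  # -1 = narrative, else missing headings
  item7_opts <- names(scheme$item7_tiers)
  wc <- c(0L, scheme$word_range[1])
  grid <- expand.grid(
    item1 = c(TRUE, FALSE), item2_word_count = wc,
    jargon = c(TRUE, FALSE), structure = structure_opts,
    item7 = item7_opts, strategy = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  if (!empty) {
    grid <- merge(grid, expand.grid(
      item9 = c(TRUE, FALSE), item10 = c(TRUE, FALSE),
      item11 = c(TRUE, FALSE), stats = c(TRUE, FALSE),
      q13_14 = c("none", "quality", "grade"), stringsAsFactors = FALSE
    ))
  }
  structured <- grid$structure >= 0L
  tibble(
    doc_id = paste0("enum", seq_len(nrow(grid))),
    is_empty_review = empty,
    item1_title_same = grid$item1,
    item2_word_count = grid$item2_word_count,
    item3_jargon = ifelse(grid$jargon, list("outcome"), list(character(0))),
    item4_structured = structured,
    item5_subtitles_recommended = ifelse(structured, grid$structure == 0L, NA),
    item6_missing_headings = ifelse(structured, grid$structure, NA_integer_),
    item7_search_date = grid$item7,
    item8_strategy = ifelse(grid$strategy, list("MEDLINE"),
                            list(character(0))),
    item9_population = if (empty) NA else grid$item9,
    item10_studies_stated = if (empty) NA else grid$item10,
    item11_participants_stated = if (empty) NA else grid$item11,
    item12_stats = if (empty) {
      list(NULL)
    } else {
      ifelse(grid$stats, list("ci"), list(character(0)))
    },
    item13_quality = if (empty) NA else grid$q13_14 != "none",
    item14_grade = if (empty) NA else grid$q13_14 == "grade"
  )
}

#' Verify a scheme's declared constants by brute-force enumeration
#'
#' Enumerates every extreme-value combination of the 14 items (coupling the
#' structure-dependent and empty-review applicability rules), scores them
#' all, and compares the achieved score range against the scheme's declared
#' per-context maxima. Also reports any divergence of the reverse-scored set
#' from the conventional `{1, 3, 8, 12}`.
#'
#' @param scheme A `pls_scheme`.
#' @return An object of class `pls_scheme_check`: a list with
#'   `max_nonempty_achieved`, `max_empty_achieved`, `min_achieved`,
#'   `maxima_ok`, `reverse_divergence`, `ok` and `n_enumerated`.
#' @examples
#' verify_scheme(default_scheme())$ok
#' @export
verify_scheme <- function(scheme = default_scheme()) {
  res <- map(c(FALSE, TRUE), function(empty) {
    enum <- enumerate_extremes(scheme, empty)
    scored <- score_assessments(enum, scheme, validate = FALSE)
    list(max = max(scored$points), min = min(scored$points),
         n = nrow(enum))
  })
  reverse_divergence <- sort(unique(c(
    setdiff(scheme$reverse_items, c(1L, 3L, 8L, 12L)),
    setdiff(c(1L, 3L, 8L, 12L), scheme$reverse_items)
  )))
  maxima_ok <- res[[1]]$max == scheme$max_nonempty &&
    res[[2]]$max == scheme$max_empty
  structure(
    list(
      max_nonempty_achieved = res[[1]]$max,
      max_empty_achieved = res[[2]]$max,
      min_achieved = min(res[[1]]$min, res[[2]]$min),
      maxima_ok = maxima_ok,
      reverse_divergence = reverse_divergence,
      ok = maxima_ok && length(reverse_divergence) == 0,
      n_enumerated = res[[1]]$n + res[[2]]$n
    ),
    class = "pls_scheme_check"
  )
}

#' @export
print.pls_scheme_check <- function(x, ...) {
  cat("<pls_scheme_check> enumerated", x$n_enumerated,
      "extreme assessments\n")
  cat("  achieved maxima:", x$max_nonempty_achieved, "(included studies),",
      x$max_empty_achieved, "(empty);",
      if (x$maxima_ok) "match declared" else "MISMATCH with declared", "\n")
  if (length(x$reverse_divergence) > 0) {
    cat("  reverse-set divergence from {1,3,8,12}:",
        paste(x$reverse_divergence, collapse = ", "), "\n")
  }
  cat(if (x$ok) "  OK\n" else "  PROBLEMS FOUND\n")
  invisible(x)
}
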