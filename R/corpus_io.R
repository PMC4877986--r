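#' Build a PLS corpus tibble
#'
#' A corpus is a tibble with one row per plain language summary (PLS) and the
#' columns listed below. `pls_corpus()` coerces and validates a data frame
#' into this shape; the readers and the synthetic generator return corpora in
#' the same shape, so all downstream verbs compose with the pipe.
#'
#' Columns:
#' * `doc_id` — unique document identifier.
#' * `review_title`, `pls_title` — the systematic-review title and the PLS
#'   title (item 1 compares them).
#' * `body` — the PLS text; heading lines start with the marker `"## "`.
#' * `pub_month` (1–12, may be `NA`), `pub_year` (may be `NA`; such documents
#'   are kept but are ineligible for the trend analysis).
#' * `review_group` — label of the review group that published the PLS.
#' * `is_empty_review` — `TRUE` when the review included no studies; this is
#'   metadata carried with the document, never inferred from the text, and it
#'   switches items 9–14 to not-applicable.
#'
#' @param x A data frame with the columns above.
#' @return A validated corpus tibble.
#' @export
pls_corpus <- function(x) {
  x <- as_tibble(x)
  required <- c("doc_id", "review_title", "pls_title", "body", "pub_month",
                "pub_year", "review_group", "is_empty_review")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("Corpus is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, required]
  x$doc_id <- as.character(x$doc_id)
  x$review_title <- as.character(x$review_title)
  x$pls_title <- as.character(x$pls_title)
  x$body <- as.character(x$body)
  x$pub_month <- as.integer(x$pub_month)
  x$pub_year <- as.integer(x$pub_year)
  x$review_group <- as.character(x$review_group)
  x$is_empty_review <- as.logical(x$is_empty_review)

  dup <- unique(x$doc_id[duplicated(x$doc_id)])
  if (length(dup) > 0) {
    stop("Duplicate doc_id in corpus: ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(x$doc_id) || any(x$doc_id == "")) {
    stop("Every document needs a non-empty doc_id.", call. = FALSE)
  }
  blank <- str_squish(x$body) == "" | is.na(x$body)
  if (any(blank)) {
    stop("Empty body for doc_id: ",
         paste(head(x$doc_id[blank], 5), collapse = ", "), call. = FALSE)
  }
  bad_month <- !is.na(x$pub_month) & (x$pub_month < 1L | x$pub_month > 12L)
  if (any(bad_month)) {
    stop("pub_month out of 1-12 for doc_id: ",
         paste(head(x$doc_id[bad_month], 5), collapse = ", "), call. = FALSE)
  }
  if (anyNA(x$is_empty_review)) {
    stop("is_empty_review must be TRUE/FALSE for every document.",
         call. = FALSE)
  }
  x
}

corpus_columns <- function() {
  c("doc_id", "review_title", "pls_title", "body", "pub_month", "pub_year",
    "review_group", "is_empty_review")
}

#' Read and write PLS corpora as JSON-lines
#'
#' One JSON object per line with the [pls_corpus()] fields; `body` is a single
#' string with embedded newlines and the `"## "` heading marker. Malformed
#' lines raise an error naming the line number; duplicate `doc_id`s are
#' rejected. `write_pls_corpus()` and `read_pls_corpus()` round-trip a corpus
#' field-for-field.
#'
#' @param path File path.
#' @return `read_pls_corpus()` returns a corpus tibble in file order.
#' @examples
#' tmp <- tempfile(fileext = ".jsonl")
#' corp <- generate_corpus(generator_config(n_docs = 3, seed = 1))$corpus
#' write_pls_corpus(corp, tmp)
#' identical(read_pls_corpus(tmp), corp)
#' @export
read_pls_corpus <- function(path) {
  if (!file.exists(path)) stop("No such corpus file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[str_trim(lines) != ""]
  if (length(lines) == 0) {
    return(pls_corpus(tibble(
      doc_id = character(), review_title = character(),
      pls_title = character(), body = character(),
      pub_month = integer(), pub_year = integer(),
      review_group = character(), is_empty_review = logical()
    )))
  }
  recs <- map(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) {
        stop("Malformed corpus record on line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    tibble(
      doc_id = as.character(rec$doc_id %||% NA_character_),
      review_title = as.character(rec$review_title %||% NA_character_),
      pls_title = as.character(rec$pls_title %||% NA_character_),
      body = as.character(rec$body %||% NA_character_),
      pub_month = as.integer(rec$pub_month %||% NA_integer_),
      pub_year = as.integer(rec$pub_year %||% NA_integer_),
      review_group = as.character(rec$review_group %||% NA_character_),
      is_empty_review = as.logical(rec$is_empty_review %||% NA)
    )
  })
  pls_corpus(bind_rows(recs))
}

#' @rdname read_pls_corpus
#' @param corpus A corpus tibble (see [pls_corpus()]).
#' @export
write_pls_corpus <- function(corpus, path) {
  corpus <- pls_corpus(corpus)
  lines <- map_chr(seq_len(nrow(corpus)), function(i) {
    rec <- as.list(corpus[i, ])
    rec <- rec[!map_lgl(rec, is.na)]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read and write ground-truth label files
#'
#' Labels record the generator-known true value of each measured item for one
#' document, keyed by `doc_id`, as JSON-lines. List-valued items (3, 8, 12:
#' matched jargon terms, strategy-leak patterns, unexplained statistical
#' patterns) are JSON arrays; not-applicable items are `null`. The label
#' columns mirror the assessment columns of [assess_corpus()].
#'
#' @param path File path.
#' @return `read_pls_labels()` returns a label tibble.
#' @export
read_pls_labels <- function(path) {
  if (!file.exists(path)) stop("No such labels file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[str_trim(lines) != ""]
  recs <- map(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) {
        stop("Malformed label record on line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    as_label_row(rec)
  })
  bind_rows(recs)
}

# one parsed JSON record -> 1-row label tibble with the assessment schema
as_label_row <- function(rec) {
  lst <- function(x) {
    if (is.null(x)) list(NULL) else list(as.character(x))
  }
  tibble(
    doc_id = as.character(rec$doc_id),
    is_empty_review = as.logical(rec$is_empty_review %||% NA),
    item1_title_same = as.logical(rec$item1_title_same %||% NA),
    item2_word_count = as.integer(rec$item2_word_count %||% NA_integer_),
    item3_jargon = lst(rec$item3_jargon),
    item4_structured = as.logical(rec$item4_structured %||% NA),
    item5_subtitles_recommended =
      as.logical(rec$item5_subtitles_recommended %||% NA),
    item6_missing_headings =
      as.integer(rec$item6_missing_headings %||% NA_integer_),
    item7_search_date = as.character(rec$item7_search_date %||% NA_character_),
    item8_strategy = lst(rec$item8_strategy),
    item9_population = as.logical(rec$item9_population %||% NA),
    item10_studies_stated = as.logical(rec$item10_studies_stated %||% NA),
    item11_participants_stated =
      as.logical(rec$item11_participants_stated %||% NA),
    item12_stats = lst(rec$item12_stats),
    item13_quality = as.logical(rec$item13_quality %||% NA),
    item14_grade = as.logical(rec$item14_grade %||% NA)
  )
}

#' @rdname read_pls_labels
#' @param labels A label tibble.
#' @export
write_pls_labels <- function(labels, path) {
  lines <- map_chr(seq_len(nrow(labels)), function(i) {
    rec <- as.list(labels[i, ])
    rec <- map(rec, function(v) if (is.list(v)) v[[1]] else v)
    # NULL list entries and NA scalars serialize as JSON null
    rec <- map(rec, function(v) if (length(v) == 1 && is.na(v)) NULL else v)
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Cross-validate labels against a corpus
#'
#' Produces a structured report rather than failing: orphan labels (no such
#' `doc_id` in the corpus), unlabeled documents, and applicability violations
#' — a label carrying a value for items 9–14 of an empty review, or for items
#' 5–6 of a narrative (unstructured) PLS.
#'
#' @param labels Label tibble (see [read_pls_labels()]).
#' @param corpus Corpus tibble.
#' @return A tibble with columns `doc_id`, `issue`, `detail`; zero rows when
#'   everything is consistent.
#' @export
validate_pls_labels <- function(labels, corpus) {
  corpus <- pls_corpus(corpus)
  issues <- list()
  orphans <- setdiff(labels$doc_id, corpus$doc_id)
  if (length(orphans) > 0) {
    issues <- c(issues, list(tibble(
      doc_id = orphans, issue = "orphan_label",
      detail = "label doc_id not present in corpus"
    )))
  }
  unlabeled <- setdiff(corpus$doc_id, labels$doc_id)
  if (length(unlabeled) > 0) {
    issues <- c(issues, list(tibble(
      doc_id = unlabeled, issue = "unlabeled_document",
      detail = "corpus document has no label record"
    )))
  }
  joined <- dplyr::inner_join(
    labels, corpus[, c("doc_id", "is_empty_review")],
    by = "doc_id", suffix = c("", ".corpus")
  )
  if (nrow(joined) > 0) {
    empty <- joined$is_empty_review.corpus
    na_listed <- function(col) map_lgl(joined[[col]], is.null)
    item_914_present <-
      !is.na(joined$item9_population) | !is.na(joined$item10_studies_stated) |
      !is.na(joined$item11_participants_stated) | !na_listed("item12_stats") |
      !is.na(joined$item13_quality) | !is.na(joined$item14_grade)
    bad <- empty & item_914_present
    if (any(bad)) {
      issues <- c(issues, list(tibble(
        doc_id = joined$doc_id[bad], issue = "applicability_violation",
        detail = "items 9-14 labeled for an empty review"
      )))
    }
    narrative <- !is.na(joined$item4_structured) & !joined$item4_structured
    item_56_present <- !is.na(joined$item5_subtitles_recommended) |
      !is.na(joined$item6_missing_headings)
    bad56 <- narrative & item_56_present
    if (any(bad56)) {
      issues <- c(issues, list(tibble(
        doc_id = joined$doc_id[bad56], issue = "applicability_violation",
        detail = "items 5-6 labeled for a narrative PLS"
      )))
    }
  }
  if (length(issues) == 0) {
    return(tibble(doc_id = character(), issue = character(),
                  detail = character()))
  }
  bind_rows(issues)
}

#' Months elapsed since the first eligible publication month
#'
#' The trend analysis regresses per-document adherence on publication time,
#' indexed in months since an origin month (default March 2013, the month the
#' current reporting standards took effect). Documents without a publication
#' month get `NA` and are excluded from the trend by default; mid-year
#' imputation (July) can be enabled explicitly.
#'
#' @param pub_year,pub_month Integer vectors.
#' @param origin_year,origin_month The origin month (index 0).
#' @param impute_midyear If `TRUE`, documents with a year but no month are
#'   assigned July of their year instead of `NA`.
#' @return Integer vector of month indices (`NA` where ineligible).
#' @examples
#' month_index(2013, 3)  # 0
#' month_index(2015, 1)  # 22
#' @export
month_index <- function(pub_year, pub_month,
                        origin_year = 2013L, origin_month = 3L,
                        impute_midyear = FALSE) {
  pub_month <- as.integer(pub_month)
  pub_year <- as.integer(pub_year)
  if (impute_midyear) {
    pub_month[is.na(pub_month) & !is.na(pub_year)] <- 7L
  }
  (pub_year - origin_year) * 12L + (pub_month - origin_month)
}

#' @rdname month_index
#' @param corpus A corpus tibble; a `month_index` column is appended.
#' @param ... Passed on to `month_index()`.
#' @export
add_month_index <- function(corpus, ...) {
  corpus$month_index <- month_index(corpus$pub_year, corpus$pub_month, ...)
  corpus
}

#' Export any document-level table to CSV
#'
#' List columns (matched terms/patterns) are flattened to `;`-separated
#' strings so the file opens in any spreadsheet tool.
#'
#' @param tbl A tibble.
#' @param path Output path.
#' @export
write_pls_csv <- function(tbl, path) {
  flat <- mutate(tbl, dplyr::across(
    dplyr::where(is.list),
    function(col) map_chr(col, function(v) paste(v, collapse = ";"))
  ))
  readr::write_csv(flat, path, na = "")
  invisible(path)
}
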