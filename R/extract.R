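#' @section Text conventions:
#' A PLS body is plain UTF-8 text. Heading lines start with the marker
#' `"## "`; everything else is prose. Detectors strip the marker before
#' matching, so heading words still count toward the word count and can carry
#' lexicon matches.
#' @name plscore-text
#' @keywords internal
NULL

strip_heading_markers <- function(body) {
  gsub("(?m)^## ", "", body, perl = TRUE)
}

# prose only: heading lines dropped entirely (a bare heading is structure,
# measured by items 4-6, not content)
prose_text <- function(body) {
  lines <- unlist(str_split(body, "\n"))
  paste(lines[!startsWith(lines, "## ")], collapse = " ")
}

body_tokens <- function(text) {
  toks <- unlist(str_split(text, "\\s+"))
  toks[toks != ""]
}

split_sentences <- function(text) {
  # ". " heuristic (plus other terminal marks and line breaks); good enough to
  # keep a search cue and an unrelated year in different sentences
  text <- gsub("\n", " ", text, fixed = TRUE)
  out <- unlist(strsplit(text, "(?<=[.!?])\\s+", perl = TRUE))
  out[str_trim(out) != ""]
}

escape_regex <- function(x) {
  gsub("([.^$|(){}\\[\\]*+?\\\\])", "\\\\\\1", x, perl = TRUE)
}

month_name_regex <- function() {
  paste0("\\b(?:january|february|march|april|may|june|july|august|",
         "september|october|november|december)\\b")
}

#' Count the words of a PLS body
#'
#' Whitespace-delimited tokens after stripping heading markers (heading words
#' count). The reporting standards recommend 400 words and allow at most 700;
#' item 2 scores a summary whose count falls in that range.
#'
#' @param body PLS body text.
#' @return Non-negative integer.
#' @examples
#' count_words("Antibiotics reduce sore throat duration.")
#' @export
count_words <- function(body) {
  if (is.na(body)) return(0L)
  length(body_tokens(strip_heading_markers(body)))
}

#' Item 1: is the PLS title identical to the review title?
#'
#' The standards want the review title *restated in plain language*, so an
#' identical title is a (reverse-scored) violation. Titles are compared after
#' normalization: case folded, whitespace collapsed, terminal punctuation
#' stripped.
#'
#' @param review_title,pls_title Non-empty title strings.
#' @return `TRUE` when the titles are the same after normalization.
#' @examples
#' title_identical("Antibiotics  for sore throat.", "antibiotics for sore throat")
#' @export
title_identical <- function(review_title, pls_title) {
  norm <- function(x) {
    x <- str_squish(str_to_lower(x))
    sub("[.?!:;,]+$", "", x)
  }
  if (is.na(review_title) || is.na(pls_title) ||
      str_squish(review_title) == "" || str_squish(pls_title) == "") {
    stop("Both titles must be non-empty.", call. = FALSE)
  }
  norm(review_title) == norm(pls_title)
}

#' Item 3: find jargon terms in a PLS body
#'
#' Case-insensitive whole-word/phrase matching against the jargon lexicon,
#' with optional plural stemming (`outcomes` matches `outcome`). Ambiguous
#' terms (words whose medical meaning differs from everyday usage) form a
#' separate tier, reported only when `include_ambiguous = TRUE` and excluded
#' from scoring by default.
#'
#' @param body PLS body text.
#' @param lexicons A [pls_lexicons()] object.
#' @param include_ambiguous Also report the ambiguous tier?
#' @param stemming Allow a trailing `s`/`es` on the final word of a term?
#' @return A tibble with columns `term` (canonical lexicon entry), `tier`
#'   (`"jargon"` or `"ambiguous"`) and `start` (character offset of the first
#'   occurrence); one row per distinct term, ordered by position.
#' @examples
#' find_jargon("The main outcome was pain; efficacy was high.", pls_lexicons())
#' @export
find_jargon <- function(body, lexicons = pls_lexicons(),
                        include_ambiguous = FALSE, stemming = TRUE) {
  text <- strip_heading_markers(body)
  tiers <- list(jargon = lexicons$jargon_terms)
  if (include_ambiguous) tiers$ambiguous <- lexicons$ambiguous_terms
  rows <- imap(tiers, function(terms, tier) {
    hits <- map(terms, function(term) {
      pat <- paste0("\\b", gsub("\\s+", "\\\\s+", escape_regex(term)),
                    if (stemming) "(?:e?s)?", "\\b")
      loc <- regexpr(pat, text, perl = TRUE, ignore.case = TRUE)
      if (loc[1] == -1) return(NULL)
      tibble(term = term, tier = tier, start = as.integer(loc[1]))
    })
    bind_rows(hits)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(term = character(), tier = character(), start = integer()))
  }
  arrange(out, .data$start)
}

#' Items 4-6: heading structure of a PLS
#'
#' A PLS is *structured* when it contains at least one heading line; the
#' standards then recommend five specific headings. Heading text is
#' normalized (case folded, trailing colon/period stripped, whitespace
#' collapsed) and matched against the recommended set, tolerating common
#' variants ("Review questions", "Quality of the evidence"). For a narrative
#' PLS the matched set and missing count are not applicable (`NA`).
#'
#' @inheritParams find_jargon
#' @param heading_heuristic Also treat unmarked short title-case lines
#'   (at most 6 words, no terminal period, initial capital) as headings; off
#'   by default because corpora written with the `"## "` marker don't need it.
#' @return One-row tibble: `structured` (logical), `matched` (list column of
#'   canonical headings found, `NA`-bearing for narrative), `missing_count`
#'   (0-5, or `NA` for narrative).
#' @export
detect_structure <- function(body, lexicons = pls_lexicons(),
                             heading_heuristic = FALSE) {
  lines <- unlist(str_split(body, "\n"))
  marked <- startsWith(lines, "## ")
  heading_text <- substring(lines[marked], 4)
  if (heading_heuristic) {
    unmarked <- str_trim(lines[!marked])
    cand <- unmarked[
      unmarked != "" &
        str_count(unmarked, "\\S+") <= 6 &
        !grepl("[.!?]$", unmarked) &
        grepl("^[A-Z]", unmarked)
    ]
    heading_text <- c(heading_text, cand)
  }
  structured <- length(heading_text) > 0
  if (!structured) {
    return(tibble(structured = FALSE, matched = list(NULL),
                  missing_count = NA_integer_))
  }
  norm <- str_squish(str_to_lower(heading_text))
  norm <- sub("[:.]+$", "", norm)
  norm <- str_trim(norm)
  canon <- unname(lexicons$heading_variants[norm])
  matched <- intersect(lexicons$recommended_headings, canon)
  n_missing <- 5L - length(matched)
  tibble(structured = TRUE, matched = list(matched),
         missing_count = n_missing)
}

#' Item 7: search-date tier
#'
#' Looks for date expressions in the same sentence as a search cue
#' ("search(ed)", "current to", "up to date"), so that unrelated years —
#' trial publication years, for instance — don't count. A month-plus-year
#' expression outranks a bare year; the highest tier found is returned.
#'
#' @param body PLS body text.
#' @return One-row tibble: `tier` (one of `"month_and_year"`, `"year_only"`,
#'   `"none"`) and `evidence` (the matching sentence, or `NA`).
#' @examples
#' detect_search_date("The evidence is current to June 2014.")
#' @export
detect_search_date <- function(body) {
  sentences <- split_sentences(strip_heading_markers(body))
  cue <- "(?i)\\b(?:search(?:ed|ing|es)?|current to|up to date|up-to-date)\\b"
  year <- "\\b(?:19|20)\\d{2}\\b"
  month <- paste0("(?i)", month_name_regex())
  tier <- "none"
  evidence <- NA_character_
  for (s in sentences) {
    if (!grepl(cue, s, perl = TRUE)) next
    has_year <- grepl(year, s, perl = TRUE)
    if (has_year && grepl(month, s, perl = TRUE)) {
      return(tibble(tier = "month_and_year", evidence = s))
    }
    if (has_year && tier == "none") {
      tier <- "year_only"
      evidence <- s
    }
  }
  tibble(tier = tier, evidence = evidence)
}

#' Item 8: search-strategy details leaked into the PLS
#'
#' The standards forbid search-strategy detail (databases, search terms) in a
#' PLS. Detects named bibliographic databases (case-sensitive, they are
#' proper names), quoted boolean search strings, `MeSH`, and explicit search
#' term lists.
#'
#' @inheritParams find_jargon
#' @return Tibble with columns `pattern` (database name or one of
#'   `"boolean_syntax"`, `"mesh"`, `"search_terms_list"`) and `start`; one
#'   row per distinct pattern.
#' @examples
#' find_strategy_details("We searched MEDLINE and EMBASE.", pls_lexicons())
#' @export
find_strategy_details <- function(body, lexicons = pls_lexicons()) {
  text <- strip_heading_markers(body)
  q <- "['\"‘’“”]"
  syntax <- c(
    boolean_syntax = paste0(q, "[^'\"‘’“”]{1,60}", q,
                            "\\s*(?:AND|OR|NOT)\\s*", q),
    mesh = "\\bMeSH\\b",
    search_terms_list = "(?i)\\bsearch terms?\\b\\s*(?::|were|included|used)"
  )
  db <- setNames(
    paste0("\\b", escape_regex(lexicons$database_names), "\\b"),
    lexicons$database_names
  )
  pats <- c(db, syntax)
  hits <- imap(pats, function(pat, name) {
    loc <- regexpr(pat, text, perl = TRUE)
    if (loc[1] == -1) return(NULL)
    tibble(pattern = name, start = as.integer(loc[1]))
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble(pattern = character(), start = integer()))
  }
  arrange(out, .data$start)
}

population_nouns <- function() {
  c("adults", "adult", "children", "child", "women", "men", "patients",
    "people", "infants", "babies", "newborns", "adolescents", "teenagers")
}

population_qualifiers <- function() {
  c("aged", "age", "ages", "years", "months", "older", "younger", "with",
    "who", "whose", "living", "undergoing", "receiving", "diagnosed",
    "suffering", "hospitalised", "hospitalized", "recovering")
}

#' Item 9: are population details given?
#'
#' True when a population noun (adults, children, women, men, patients,
#' people, ...) is qualified — by age, condition or similar — within the next
#' six tokens, or directly preceded by a qualifying adjective such as
#' "pregnant". A drug-versus-drug sentence with no people in it does not
#' count.
#'
#' @param body PLS body text.
#' @return Logical scalar.
#' @examples
#' detect_population_details("We included adults aged over 65 with diabetes.")
#' @export
detect_population_details <- function(body) {
  toks <- body_tokens(strip_heading_markers(body))
  toks <- gsub("[^a-z0-9-]", "", str_to_lower(toks))
  nouns <- population_nouns()
  quals <- population_qualifiers()
  idx <- which(toks %in% nouns)
  for (i in idx) {
    ahead <- toks[seq(i + 1L, min(i + 6L, length(toks)))]
    if (i < length(toks) && any(ahead %in% quals)) return(TRUE)
    if (i > 1L && toks[i - 1L] %in% c("pregnant", "older", "elderly")) {
      return(TRUE)
    }
  }
  FALSE
}

spelled_numbers <- function() {
  setNames(1:20, c("one", "two", "three", "four", "five", "six", "seven",
                   "eight", "nine", "ten", "eleven", "twelve", "thirteen",
                   "fourteen", "fifteen", "sixteen", "seventeen", "eighteen",
                   "nineteen", "twenty"))
}

#' Items 10-11: number of studies / participants stated?
#'
#' Matches a numeral (with optional thousands separators) or a spelled-out
#' number (one...twenty) followed — within at most two intervening tokens —
#' by a kind-specific noun (`studies`/`trials`/`RCTs`, or
#' `participants`/`patients`/`people`/...). "We found no trials" counts as a
#' stated study count of zero (configurable), since it does convey the
#' number.
#'
#' @param body PLS body text.
#' @param kind `"studies"` or `"participants"`.
#' @param count_none_as_stated Treat "no studies"/"no trials" as a stated
#'   count of 0?
#' @return One-row tibble: `stated` (logical), `value` (integer; `NA` when
#'   nothing was matched).
#' @examples
#' detect_count_statement("We included 12 studies (2,317 participants).", "studies")
#' @export
detect_count_statement <- function(body, kind = c("studies", "participants"),
                                   count_none_as_stated = TRUE) {
  kind <- match.arg(kind)
  text <- strip_heading_markers(body)
  nouns <- switch(kind,
    studies = "(?:studies|study|trials|trial|RCTs|randomi[sz]ed trials)",
    participants = paste0("(?:participants|patients|people|volunteers|",
                          "subjects|individuals|enrollees)")
  )
  spelled <- spelled_numbers()
  num <- paste0("(?:\\d{1,3}(?:,\\d{3})+|\\d+|",
                paste(names(spelled), collapse = "|"), ")")
  pat <- paste0("(?i)\\b(", num, ")\\s+(?:[-A-Za-z]+\\s+){0,2}?", nouns, "\\b")
  loc <- regexpr(pat, text, perl = TRUE)
  zero_pat <- paste0("(?i)\\bno\\s+(?:further\\s+)?", nouns, "\\b")
  zero_loc <- if (count_none_as_stated) {
    regexpr(zero_pat, text, perl = TRUE)
  } else {
    -1L
  }
  num_start <- if (loc[1] == -1) Inf else loc[1]
  zero_start <- if (zero_loc[1] == -1) Inf else zero_loc[1]
  if (is.infinite(num_start) && is.infinite(zero_start)) {
    return(tibble(stated = FALSE, value = NA_integer_))
  }
  if (zero_start < num_start) {
    return(tibble(stated = TRUE, value = 0L))
  }
  raw <- regmatches(text, loc)[[1]]
  raw_num <- sub(pat, "\\1", raw, perl = TRUE)
  raw_num <- gsub(",", "", raw_num)
  value <- if (grepl("^\\d+$", raw_num)) {
    as.integer(raw_num)
  } else {
    unname(spelled[str_to_lower(raw_num)])
  }
  tibble(stated = TRUE, value = as.integer(value))
}

#' Item 12: complex statistical data without an explanation
#'
#' Matches the statistical-notation patterns of the lexicon (odds/risk/hazard
#' ratios, SMD, MD, confidence intervals — each requiring a numeric value in
#' the same clause). A match is *suppressed* — treated as explained — when an
#' explanation cue ("this means", "in other words", "out of 1000", ...)
#' starts within `window` tokens after it.
#'
#' @inheritParams find_jargon
#' @param window Suppression window in tokens after the match (default 12).
#' @return Tibble with columns `pattern` and `start`: the distinct
#'   unexplained pattern classes found.
#' @examples
#' find_unexplained_stats("Pain fell (SMD -0.41, 95 % CI -0.62 to -0.21).",
#'                        pls_lexicons())
#' @export
find_unexplained_stats <- function(body, lexicons = pls_lexicons(),
                                   window = 12L) {
  text <- strip_heading_markers(body)
  cue_pat <- paste0("(?i)(?:this means|which means|in other words|that is,|",
                    "put simply|meaning that|out of (?:a )?1,?000|",
                    "in (?:every )?1,?000|in (?:every )?100\\b)")
  cue_loc <- gregexpr(cue_pat, text, perl = TRUE)[[1]]
  cue_starts <- if (cue_loc[1] == -1) integer(0) else as.integer(cue_loc)
  suppressed <- function(match_end) {
    if (length(cue_starts) == 0) return(FALSE)
    after <- cue_starts[cue_starts > match_end]
    any(map_lgl(after, function(cs) {
      gap <- substr(text, match_end + 1L, cs - 1L)
      str_count(gap, "\\S+") <= window
    }))
  }
  hits <- imap(lexicons$stat_patterns, function(pat, name) {
    loc <- gregexpr(pat, text, perl = TRUE)[[1]]
    if (loc[1] == -1) return(NULL)
    ends <- as.integer(loc) + attr(loc, "match.length") - 1L
    keep <- !map_lgl(ends, suppressed)
    if (!any(keep)) return(NULL)
    tibble(pattern = name, start = as.integer(loc)[keep][1])
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble(pattern = character(), start = integer()))
  }
  arrange(out, .data$start)
}

#' Items 13-14: is evidence quality addressed, and via GRADE?
#'
#' Quality is addressed when any quality phrase matches (case-insensitive)
#' in the prose; heading lines are excluded, so the bare recommended heading
#' "Quality of evidence" counts as structure (items 4-6), not as content.
#' GRADE must appear as a whole capitalized word ("We graded the essays"
#' does not count). A GRADE mention implies that quality is addressed.
#'
#' @inheritParams find_jargon
#' @return One-row tibble: `quality_addressed`, `grade_mentioned` (logicals).
#' @examples
#' detect_quality_statement("We rated certainty using GRADE.", pls_lexicons())
#' @export
detect_quality_statement <- function(body, lexicons = pls_lexicons()) {
  text <- prose_text(body)
  quality <- any(map_lgl(lexicons$quality_phrases, function(p) {
    grepl(paste0("(?i)", p), text, perl = TRUE)
  }))
  grade <- grepl("\\bGRADE\\b", text, perl = TRUE)
  tibble(quality_addressed = quality || grade, grade_mentioned = grade)
}

assessment_items <- function() {
  c("item1_title_same", "item2_word_count", "item3_jargon",
    "item4_structured", "item5_subtitles_recommended",
    "item6_missing_headings", "item7_search_date", "item8_strategy",
    "item9_population", "item10_studies_stated",
    "item11_participants_stated", "item12_stats", "item13_quality",
    "item14_grade")
}

#' Assess one PLS document against all 14 measured items
#'
#' Composes the individual detectors and enforces the applicability rules:
#' items 9-14 are not applicable (`NA`) for the PLS of an empty review, and
#' items 5-6 are not applicable for a narrative (unstructured) PLS. A fully
#' recommended structure records `item6_missing_headings = 0`.
#'
#' @param doc A one-row corpus tibble (or named list) with the
#'   [pls_corpus()] fields.
#' @param lexicons A [pls_lexicons()] object.
#' @param include_ambiguous Count ambiguous-tier terms as jargon for item 3?
#' @param stemming,heading_heuristic,suppression_window,count_none_as_stated
#'   Passed to the respective detectors.
#' @return A one-row assessment tibble; see [assess_corpus()] for the schema.
#' @export
assess_pls <- function(doc, lexicons = pls_lexicons(),
                       include_ambiguous = FALSE, stemming = TRUE,
                       heading_heuristic = FALSE, suppression_window = 12L,
                       count_none_as_stated = TRUE) {
  doc <- as.list(doc)
  empty <- isTRUE(doc$is_empty_review)
  body <- doc$body

  jarg <- find_jargon(body, lexicons, include_ambiguous = TRUE,
                      stemming = stemming)
  scored_terms <- jarg$term[jarg$tier == "jargon" |
                              (include_ambiguous & jarg$tier == "ambiguous")]
  ambiguous_terms <- jarg$term[jarg$tier == "ambiguous"]
  struct <- detect_structure(body, lexicons,
                             heading_heuristic = heading_heuristic)
  date <- detect_search_date(body)
  strat <- find_strategy_details(body, lexicons)

  if (empty) {
    item9 <- NA
    item10 <- NA
    item11 <- NA
    stats_found <- NULL
    item13 <- NA
    item14 <- NA
  } else {
    item9 <- detect_population_details(body)
    item10 <- detect_count_statement(
      body, "studies", count_none_as_stated = count_none_as_stated)$stated
    item11 <- detect_count_statement(
      body, "participants", count_none_as_stated = count_none_as_stated)$stated
    stats_found <- find_unexplained_stats(body, lexicons,
                                          window = suppression_window)$pattern
    qual <- detect_quality_statement(body, lexicons)
    item13 <- qual$quality_addressed
    item14 <- qual$grade_mentioned
  }

  tibble(
    doc_id = as.character(doc$doc_id),
    is_empty_review = empty,
    item1_title_same = title_identical(doc$review_title, doc$pls_title),
    item2_word_count = count_words(body),
    item3_jargon = list(as.character(scored_terms)),
    item3_ambiguous = list(as.character(ambiguous_terms)),
    item4_structured = struct$structured,
    item5_subtitles_recommended = if (struct$structured) {
      struct$missing_count == 0L
    } else {
      NA
    },
    item6_missing_headings = if (struct$structured) {
      struct$missing_count
    } else {
      NA_integer_
    },
    item7_search_date = date$tier,
    item8_strategy = list(as.character(strat$pattern)),
    item9_population = item9,
    item10_studies_stated = item10,
    item11_participants_stated = item11,
    item12_stats = if (empty) list(NULL) else list(as.character(stats_found)),
    item13_quality = item13,
    item14_grade = item14
  )
}

#' Assess every document of a corpus
#'
#' @param corpus A corpus tibble (see [pls_corpus()]).
#' @inheritParams assess_pls
#' @return A tibble with one row per document: `doc_id`, `is_empty_review`,
#'   and the 14 item columns (`item1_title_same`, `item2_word_count`,
#'   `item3_jargon` + `item3_ambiguous` list columns, `item4_structured`,
#'   `item5_subtitles_recommended`, `item6_missing_headings`,
#'   `item7_search_date`, `item8_strategy`, `item9_population`,
#'   `item10_studies_stated`, `item11_participants_stated`, `item12_stats`,
#'   `item13_quality`, `item14_grade`). Not-applicable values are `NA`
#'   (scalars) or `NULL` (list columns).
#' @examples
#' gen <- generate_corpus(generator_config(n_docs = 5, seed = 1))
#' assess_corpus(gen$corpus)
#' @export
assess_corpus <- function(corpus, lexicons = pls_lexicons(), ...) {
  corpus <- pls_corpus(corpus)
  rows <- map(seq_len(nrow(corpus)),
              function(i) assess_pls(corpus[i, ], lexicons, ...))
  bind_rows(rows)
}

#' Per-item agreement between assessments and ground-truth labels
#'
#' Joins on `doc_id` and compares each of the 14 items; scalar items agree
#' when equal (with `NA` matching `NA`, i.e. both sides must call the item
#' not-applicable), list-valued items (3, 8, 12) when they contain the same
#' set of matched terms/patterns.
#'
#' @param assessments Output of [assess_corpus()].
#' @param labels A label tibble (see [read_pls_labels()]).
#' @return Tibble with columns `item`, `n`, `n_agree`, `agreement`.
#' @export
compare_assessments <- function(assessments, labels) {
  joined <- dplyr::inner_join(assessments, labels, by = "doc_id",
                              suffix = c("", ".lab"))
  if (nrow(joined) == 0) stop("No shared doc_ids to compare.", call. = FALSE)
  scalar_eq <- function(a, b) {
    (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  }
  set_eq <- function(a, b) {
    map2_l <- function(x, y) {
      if (is.null(x) && is.null(y)) return(TRUE)
      if (is.null(x) || is.null(y)) return(FALSE)
      setequal(x, y)
    }
    map_lgl(seq_along(a), function(i) map2_l(a[[i]], b[[i]]))
  }
  list_items <- c("item3_jargon", "item8_strategy", "item12_stats")
  rows <- map(assessment_items(), function(item) {
    agree <- if (item %in% list_items) {
      set_eq(joined[[item]], joined[[paste0(item, ".lab")]])
    } else {
      scalar_eq(joined[[item]], joined[[paste0(item, ".lab")]])
    }
    tibble(item = item, n = length(agree), n_agree = sum(agree),
           agreement = mean(agree))
  })
  bind_rows(rows)
}
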