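#' Default lexicons for PLS item detection
#'
#' The rule-based detectors are driven by a set of small lexicons: jargon
#' terms a plain language summary (PLS) should avoid, an "ambiguous" tier of
#' words whose everyday meaning differs from their technical meaning,
#' bibliographic database names that betray search-strategy detail, regular
#' expressions for complex statistical notation, phrases that address the
#' quality of the evidence, and the five recommended section headings for a
#' structured PLS (Review question, Background, Study characteristics, Key
#' results, Quality of evidence).
#'
#' Every component can be overridden, either by passing modified vectors here
#' or by loading a plain-text lexicon file with [read_lexicons()]. Ambiguous
#' terms are reported in their own tier and are excluded from scoring unless
#' explicitly requested, since their presence is context-dependent rather
#' than forbidden outright.
#'
#' @param jargon_terms Character vector of jargon words/phrases (matched
#'   case-insensitively, whole word, optional plural stemming).
#' @param ambiguous_terms Character vector of ambiguous-tier words.
#' @param database_names Character vector of database names, matched
#'   case-sensitively (they are proper names / acronyms).
#' @param stat_patterns Named character vector of Perl regular expressions
#'   for statistical notation; names label the pattern class.
#' @param quality_phrases Character vector of case-insensitive regular
#'   expressions signalling that evidence quality is addressed.
#' @param recommended_headings Character vector of exactly 5 canonical
#'   headings for a structured PLS.
#' @param heading_variants Named character vector mapping normalized heading
#'   variants (lower case, no trailing colon) to canonical headings.
#'
#' @return An object of class `pls_lexicons` (a named list).
#' @examples
#' lex <- pls_lexicons()
#' lex$recommended_headings
#' @export
pls_lexicons <- function(jargon_terms = c("outcome", "literature",
                                          "case series", "efficacy",
                                          "effect size"),
                         ambiguous_terms = c("local", "blinding", "control",
                                             "practice"),
                         database_names = c("MEDLINE", "EMBASE", "CENTRAL",
                                            "CINAHL", "PsycINFO", "PubMed",
                                            "Scopus", "LILACS", "AMED"),
                         stat_patterns = default_stat_patterns(),
                         quality_phrases = default_quality_phrases(),
                         recommended_headings = c("Review question",
                                                  "Background",
                                                  "Study characteristics",
                                                  "Key results",
                                                  "Quality of evidence"),
                         heading_variants = default_heading_variants()) {
  if (length(recommended_headings) != 5L) {
    stop("`recommended_headings` must contain exactly 5 headings.",
         call. = FALSE)
  }
  if (is.null(names(stat_patterns)) || any(names(stat_patterns) == "")) {
    stop("`stat_patterns` must be a fully named character vector.",
         call. = FALSE)
  }
  structure(
    list(
      jargon_terms = jargon_terms,
      ambiguous_terms = ambiguous_terms,
      database_names = database_names,
      stat_patterns = stat_patterns,
      quality_phrases = quality_phrases,
      recommended_headings = recommended_headings,
      heading_variants = heading_variants
    ),
    class = "pls_lexicons"
  )
}

# Statistical-notation classes. Acronyms (OR, RR, SMD, MD, HR, CI) are matched
# case-sensitively so prose words ("or") cannot fire; spelled-out names are
# case-insensitive. Each ratio/difference pattern requires a numeric value
# within the same clause, so a bare mention ("we report risk ratios") does not
# count as complex statistical data.
default_stat_patterns <- function() {
  num <- "[^.;]{0,20}?-?\\d"
  c(
    odds_ratio = paste0("(?:(?i:\\bodds ratios?\\b)|\\bOR\\b)", num),
    risk_ratio = paste0("(?:(?i:\\brisk ratios?\\b)|\\bRR\\b)", num),
    hazard_ratio = paste0("(?:(?i:\\bhazard ratios?\\b)|\\bHR\\b)", num),
    smd = paste0("(?:(?i:\\bstandardi[sz]ed mean differences?\\b)|\\bSMD\\b)",
                 num),
    mean_difference = paste0("\\bMD\\b", num),
    ci = "(?:\\b(?:90|95|99)\\s?%\\s?(?:CI\\b|(?i:confidence interval))|(?i:\\bconfidence intervals?\\b))"
  )
}

default_quality_phrases <- function() {
  c(
    "quality of (the )?(evidence|included studies|studies|trials)",
    "certainty of (the )?evidence",
    "risk of bias",
    "\\b(very low|low|moderate|high)[- ]quality\\b",
    "methodological quality"
  )
}

default_heading_variants <- function() {
  c(
    "review question" = "Review question",
    "review questions" = "Review question",
    "background" = "Background",
    "study characteristics" = "Study characteristics",
    "key results" = "Key results",
    "quality of evidence" = "Quality of evidence",
    "quality of the evidence" = "Quality of evidence"
  )
}

#' Read or write lexicons as a sectioned plain-text file
#'
#' The file format is INI-like: a `[section]` line opens one of the lexicon
#' components, and each following non-blank line is one entry. For
#' `stat_patterns` and `heading_variants`, entries are `name = value` pairs.
#' Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return For `read_lexicons`, a `pls_lexicons` object; unspecified sections
#'   fall back to the defaults.
#' @seealso [pls_lexicons()]
#' @export
read_lexicons <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- str_trim(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  section <- NA_character_
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      out[[section]] <- character(0)
    } else {
      if (is.na(section)) {
        stop("Lexicon file must open with a [section] line.", call. = FALSE)
      }
      if (section %in% c("stat_patterns", "heading_variants")) {
        kv <- regmatches(ln, regexec("^([^=]+?)\\s*=\\s*(.+)$", ln))[[1]]
        if (length(kv) != 3L) {
          stop("Section [", section, "] requires 'name = value' lines.",
               call. = FALSE)
        }
        out[[section]] <- c(out[[section]], setNames(kv[3], str_trim(kv[2])))
      } else {
        out[[section]] <- c(out[[section]], ln)
      }
    }
  }
  args <- out[intersect(names(out), names(formals(pls_lexicons)))]
  do.call(pls_lexicons, args)
}

#' @rdname read_lexicons
#' @param lex A `pls_lexicons` object.
#' @export
write_lexicons <- function(lex, path) {
  stopifnot(inherits(lex, "pls_lexicons"))
  chunks <- imap(unclass(lex), function(entries, section) {
    body <- if (is.null(names(entries))) {
      entries
    } else {
      paste(names(entries), "=", entries)
    }
    c(paste0("[", section, "]"), body, "")
  })
  writeLines(unlist(chunks), path, useBytes = TRUE)
  invisible(path)
}
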