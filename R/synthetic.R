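#' Configuration for the synthetic PLS generator
#'
#' The generator emits labelled plain-language-summary corpora whose default
#' parameters emulate the published corpus: roughly one in ten reviews is
#' empty, about a third of summaries are structured, per-item adherence rates
#' follow the published adherence table, word counts follow a right-skewed
#' distribution with mean 319 and minimum 46, publication months span the 23
#' months from March 2013 to January 2015, and a small positive
#' adherence-probability trend over time can be injected. All of it is
#' overridable.
#'
#' @param n_docs Number of documents.
#' @param empty_fraction Probability a document reports an empty review.
#' @param rates Named adherence probabilities for the Bernoulli items
#'   (`item1`, `item3`, `item4`, `item8`, `item9`, `item10`, `item11`,
#'   `item12`, `item13`, `item14`); `item1`/`item3`/`item8`/`item12` are the
#'   probability the *offending element is absent* (the reverse-scored
#'   items). Item 2 has no free rate: it follows from the word-count
#'   distribution. Missing entries keep their defaults.
#' @param item6_dist Probabilities over 0-5 missing headings for a
#'   structured PLS (first entry = fully recommended, which is also item 5).
#' @param item7_probs Probabilities over the search-date tiers
#'   (`month_and_year`, `year_only`, `none`).
#' @param word_mean,word_sd,word_min Word-count distribution: a gamma
#'   distribution with the given mean and sd, shifted to start at
#'   `word_min`.
#' @param groups Tibble with `label` and `offset`: review groups and their
#'   additive shift on the Bernoulli adherence rates (group heterogeneity).
#' @param trend_slope Additive change in each shifted item's adherence
#'   probability per month (centred on the middle of `month_range`).
#' @param month_range Integer vector of available publication-month indices
#'   (0 = March 2013; see [month_index()]).
#' @param noise `"clean"` (every item realized with detector-guaranteed
#'   phrasing) or `"noisy"` (paraphrase variants, a small fraction of which
#'   are deliberately beyond the detectors' reach).
#' @param hard_fraction In noisy mode, the probability that an applicable
#'   item uses such an adversarial paraphrase (items 3, 7, 9, 10).
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   corpus byte for byte.
#' @return An object of class `pls_generator_config`.
#' @export
generator_config <- function(n_docs,
                             empty_fraction = 176 / 1738,
                             rates = c(),
                             item6_dist = c(217, 141, 90, 47, 40, 94) / 629,
                             item7_probs = c(month_and_year = 992,
                                             year_only = 20,
                                             none = 726) / 1738,
                             word_mean = 319,
                             word_sd = 130,
                             word_min = 46,
                             groups = default_groups(),
                             trend_slope = 0.003,
                             month_range = 0:22,
                             noise = c("clean", "noisy"),
                             hard_fraction = 0.03,
                             seed = 1L) {
  noise <- match.arg(noise)
  default_rates <- c(item1 = 0.64, item3 = 0.43, item4 = 0.36,
                     item8 = 0.99, item9 = 0.15, item10 = 0.91,
                     item11 = 0.77, item12 = 0.98, item13 = 0.56,
                     item14 = 0.007)
  if (length(rates) > 0) {
    unknown <- setdiff(names(rates), names(default_rates))
    if (length(unknown) > 0) {
      stop("Unknown rate names: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    default_rates[names(rates)] <- rates
  }
  cfg <- list(
    n_docs = as.integer(n_docs),
    empty_fraction = empty_fraction,
    rates = default_rates,
    item6_dist = item6_dist / sum(item6_dist),
    item7_probs = item7_probs / sum(item7_probs),
    word_mean = word_mean, word_sd = word_sd, word_min = word_min,
    groups = as_tibble(groups),
    trend_slope = trend_slope,
    month_range = as.integer(month_range),
    noise = noise,
    hard_fraction = hard_fraction,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "pls_generator_config")
}

default_groups <- function() {
  tibble(
    label = c("Airways", "Dermatology", "Musculoskeletal", "Neonatal",
              "Oral Health", "Stroke"),
    offset = c(-0.12, -0.06, 0, 0.02, 0.08, 0.12)
  )
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$empty_fraction, cfg$rates, cfg$item6_dist, cfg$item7_probs,
             cfg$hard_fraction)
  if (any(probs < 0 | probs > 1) || anyNA(probs)) {
    stop("All generator probabilities must lie in [0, 1].", call. = FALSE)
  }
  if (cfg$n_docs < 1) stop("n_docs must be >= 1.", call. = FALSE)
  if (length(cfg$month_range) == 0) {
    stop("month_range must be non-empty.", call. = FALSE)
  }
  if (length(cfg$item6_dist) != 6) {
    stop("item6_dist needs 6 entries (0-5 missing headings).", call. = FALSE)
  }
  if (cfg$word_sd <= 0 && cfg$word_mean > cfg$word_min) {
    stop("word_sd must be positive when word_mean > word_min.", call. = FALSE)
  }
  if (cfg$word_mean <= cfg$word_min) {
    stop("word_mean must exceed word_min.", call. = FALSE)
  }
  if (!all(c("label", "offset") %in% names(cfg$groups)) ||
      nrow(cfg$groups) == 0) {
    stop("groups needs columns `label`, `offset` and at least one row.",
         call. = FALSE)
  }
  if (cfg$rates["item14"] > cfg$rates["item13"]) {
    stop("rate for item14 (GRADE) cannot exceed the rate for item13.",
         call. = FALSE)
  }
  invisible(cfg)
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

gen_vocab <- function() {
  list(
    interventions = c("Acupuncture", "Antibiotics", "Exercise therapy",
                      "Massage", "Vitamin D supplements", "Honey",
                      "Relaxation training", "Compression stockings"),
    conditions = c("migraine", "asthma", "eczema", "low back pain",
                   "insomnia", "knee osteoarthritis", "hay fever",
                   "leg cramps"),
    months = c("January", "February", "March", "April", "May", "June",
               "July", "August", "September", "October", "November",
               "December"),
    fillers = c(
      "These findings summarise the best available evidence.",
      "Readers should bear in mind the limits of this summary.",
      "The review team followed standard Cochrane methods.",
      "Decisions about care should be made together with a health professional.",
      "This summary was written for a general audience.",
      "Future updates may add further information."
    ),
    flex_words = c("Overall", "these", "broad", "general", "findings",
                   "should", "be", "read", "carefully", "and", "interpreted",
                   "with", "due", "caution", "over", "time")
  )
}

flex_sentence <- function(n_words) {
  words <- gen_vocab()$flex_words
  stopifnot(n_words >= 1)
  picked <- rep(words, length.out = n_words)
  paste0(paste(picked, collapse = " "), ".")
}

# pad prose so the final body lands within 5 tokens of the drawn target
pad_sentences <- function(sentences, current_count, target) {
  fillers <- gen_vocab()$fillers
  i <- 1L
  while ((gap <- target - current_count) > 5L) {
    if (gap >= 16L) {
      s <- fillers[((i - 1L) %% length(fillers)) + 1L]
      i <- i + 1L
    } else {
      s <- flex_sentence(gap)
    }
    sentences <- c(sentences, s)
    current_count <- current_count + str_count(s, "\\S+")
  }
  sentences
}

pick <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

shift_rate <- function(p, delta) pmin(1, pmax(0, p + delta))

# items whose adherence probability moves with review group and time
shifted_items <- function() {
  c("item1", "item3", "item8", "item9", "item10", "item11", "item12",
    "item13")
}

draw_participant_count <- function() {
  # keep clear of 4-digit year lookalikes (1900-2100)
  pool <- c(120:1800, 2200:9000)
  pool[sample.int(length(pool), 1L)]
}

#' Generate a labelled synthetic PLS corpus
#'
#' Draws per-document item values from the configured rates (with group- and
#' time-dependent shifts), realizes each value as templated sentences —
#' headings included or omitted, jargon injected or withheld, dated search
#' statements by tier, study/participant counts, statistical notation with
#' or without an explanation cue, quality/GRADE statements — pads the prose
#' to the drawn word-count target, and records the drawn values as
#' ground-truth labels. In clean mode every realization is recoverable by
#' the bundled detectors; noisy mode mixes in paraphrases, a configurable
#' small fraction of which are deliberately adversarial.
#'
#' @param config A [generator_config()].
#' @return A list with `corpus` (a [pls_corpus()] tibble), `labels` (the
#'   ground-truth tibble, same schema as [assess_corpus()] minus the
#'   ambiguous tier), and `config`.
#' @examples
#' gen <- generate_corpus(generator_config(n_docs = 3, seed = 42))
#' gen$corpus$doc_id
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "pls_generator_config"))
  with_local_seed(config$seed, {
    rows <- map(seq_len(config$n_docs),
                function(i) generate_one(i, config))
    corpus <- pls_corpus(bind_rows(map(rows, "doc")))
    labels <- bind_rows(map(rows, "label"))
    list(corpus = corpus, labels = labels, config = config)
  })
}

generate_one <- function(i, cfg) {
  voc <- gen_vocab()
  noisy <- cfg$noise == "noisy"
  hard <- function() noisy && runif(1) < cfg$hard_fraction

  group_i <- sample.int(nrow(cfg$groups), 1L)
  group <- cfg$groups$label[group_i]
  month <- pick(cfg$month_range)
  delta <- cfg$groups$offset[group_i] +
    cfg$trend_slope * (month - mean(cfg$month_range))
  r <- cfg$rates
  r[shifted_items()] <- shift_rate(r[shifted_items()], delta)

  empty <- runif(1) < cfg$empty_fraction
  intervention <- pick(voc$interventions)
  condition <- pick(voc$conditions)
  int_l <- str_to_lower(intervention)

  # --- item draws ------------------------------------------------------
  adh <- function(item) runif(1) < r[[item]]
  item1_same <- !adh("item1")          # adherent = title restated
  has_jargon <- !adh("item3")
  structured <- adh("item4")
  missing <- if (structured) sample(0:5, 1L, prob = cfg$item6_dist) else NA_integer_
  tier <- sample(names(cfg$item7_probs), 1L, prob = cfg$item7_probs)
  has_leak <- !adh("item8")
  if (!empty) {
    pop <- adh("item9")
    n_stud <- adh("item10")
    n_part <- adh("item11")
    has_stats <- !adh("item12")
    grade <- adh("item14")
    quality <- grade ||
      runif(1) < max(0, (r[["item13"]] - r[["item14"]]) / (1 - r[["item14"]]))
  } else {
    pop <- n_stud <- n_part <- quality <- grade <- NA
    has_stats <- NA
  }

  # --- titles ----------------------------------------------------------
  review_title <- paste(intervention, "for", condition)
  pls_title <- if (item1_same) {
    review_title
  } else {
    pick(c(
      paste0("Does ", int_l, " help with ", condition, "?"),
      paste(intervention, "as a treatment for", condition),
      paste0("Can ", int_l, " improve ", condition, "?")
    ))
  }

  # --- section prose ---------------------------------------------------
  question <- pick(c(
    paste0("This review asked whether ", int_l, " works for ", condition, "."),
    paste0("We wanted to find out whether ", int_l, " helps with ",
           condition, "."),
    paste0("The aim of this review was to assess ", int_l, " for ",
           condition, ".")
  ))
  background <- pick(c(
    paste0(toupper(substring(condition, 1, 1)), substring(condition, 2),
           " is a common problem that affects daily life."),
    paste0("Many treatments have been suggested for ", condition, "."),
    paste0(intervention, " is widely used, but its benefits are uncertain.")
  ))

  date_sentence <- switch(
    tier,
    month_and_year = {
      m <- pick(voc$months)
      y <- pick(2013:2015)
      if (hard()) {
        # adversarial: a season instead of a month; detectors see year_only
        paste0("The most recent search took place in the spring of ", y, ".")
      } else {
        pick(c(
          paste0("The evidence is current to ", m, " ", y, "."),
          paste0("We searched for studies up to ", pick(1:28), " ", m, " ",
                 y, "."),
          paste0("We last searched for evidence in ", m, " ", y, ".")
        ))
      }
    },
    year_only = pick(c(
      paste0("We searched medical databases in ", pick(2013:2015), "."),
      paste0("Our search covered studies published up to ", pick(2013:2015),
             ".")
    )),
    none = pick(c(
      "We carried out a wide search for relevant evidence.",
      "We looked for all available studies on this question."
    ))
  )

  leak <- NULL
  leak_label <- character(0)
  if (has_leak) {
    choice <- pick(1:3)
    if (choice == 1) {
      leak <- "We searched MEDLINE and EMBASE for relevant trials."
      leak_label <- c("MEDLINE", "EMBASE")
    } else if (choice == 2) {
      leak <- "Our search covered CENTRAL and CINAHL."
      leak_label <- c("CENTRAL", "CINAHL")
    } else {
      leak <- paste0("We used the search terms: '", condition,
                     "' AND 'treatment'.")
      leak_label <- c("boolean_syntax", "search_terms_list")
    }
  }

  characteristics <- character(0)
  results <- character(0)
  quality_prose <- character(0)
  stats_label <- character(0)
  if (empty) {
    characteristics <- pick(c(
      "We found no studies that met the inclusion criteria.",
      "No eligible studies were identified for this review."
    ))
    results <- "No conclusions could be reached because no studies were available."
    # keeps the section (and any drawn heading) present; items 9-14 are
    # not applicable here, so wording is unconstrained
    quality_prose <- "No evidence was available to judge."
  } else {
    if (pop) {
      characteristics <- c(characteristics, if (hard()) {
        paste0("Elderly volunteers living with ", condition, " took part.")
      } else {
        pick(c(
          paste0("We included adults aged over 65 with ", condition, "."),
          paste0("The studies involved women with ", condition,
                 " who were otherwise healthy."),
          paste0("Children younger than 12 years with ", condition,
                 " took part in the studies.")
        ))
      })
    } else {
      characteristics <- c(characteristics, pick(c(
        paste0("The included studies compared ", int_l, " with usual care."),
        "This review assessed one treatment compared with another.",
        paste0("Different settings and ways of giving ", int_l,
               " were covered.")
      )))
    }
    if (n_stud && n_part) {
      ns <- pick(2:95)
      np <- draw_participant_count()
      characteristics <- c(characteristics, if (hard()) {
        paste0("The studies, numbering twenty-three in all, included ",
               format(np, big.mark = ","), " participants.")
      } else {
        pick(c(
          paste0("We included ", ns, " studies (",
                 format(np, big.mark = ","), " participants)."),
          paste0("We included ", ns, " studies with ", np,
                 " participants in total.")
        ))
      })
    } else if (n_stud) {
      characteristics <- c(characteristics, if (hard()) {
        "The studies, numbering twenty-three in all, contributed data."
      } else {
        pick(c(
          paste0("We included ", pick(2:95), " studies."),
          paste0(names(spelled_numbers())[pick(2:20)] |>
                   (\(w) paste0(toupper(substring(w, 1, 1)),
                                substring(w, 2)))(),
                 " trials met the inclusion criteria."),
          if (!n_part) "We found no trials that answered this question directly."
        ))
      })
    } else if (n_part) {
      characteristics <- c(characteristics, pick(c(
        paste0("The trials involved ", draw_participant_count(),
               " participants altogether."),
        paste0("Altogether ", draw_participant_count(),
               " participants took part."),
        paste0("Data were available for ", draw_participant_count(),
               " participants.")
      )))
    } else {
      characteristics <- c(characteristics, pick(c(
        "Several studies were included in this review.",
        "A number of trials contributed information."
      )))
      characteristics <- c(characteristics,
                           "The sizes of the included studies were not clearly reported.")
    }

    if (has_stats) {
      choice <- pick(1:3)
      if (choice == 1) {
        results <- "Pain scores fell with treatment (SMD -0.41, 95 % CI -0.62 to -0.21)."
        stats_label <- c("smd", "ci")
      } else if (choice == 2) {
        results <- "The odds ratio was 0.75 (95 % CI 0.60 to 0.93)."
        stats_label <- c("odds_ratio", "ci")
      } else {
        results <- "Symptoms improved (RR 0.80, 95 % CI 0.66 to 0.97)."
        stats_label <- c("risk_ratio", "ci")
      }
    } else {
      results <- pick(c(
        "Those given the treatment generally felt better.",
        "The treatment group improved more than the comparison group.",
        paste0("The risk ratio was 0.80; this means the chance of ",
               "improvement was about one fifth higher.")
      ))
    }

    if (quality) {
      quality_prose <- if (grade) {
        "We assessed the quality of the evidence using the GRADE approach."
      } else {
        pick(c(
          "The quality of the evidence was moderate overall.",
          "We judged the included studies to be at low risk of bias."
        ))
      }
    } else {
      quality_prose <- pick(c(
        "Further research may change these findings.",
        "More studies are likely to be carried out in this area."
      ))
    }
  }

  jargon_label <- character(0)
  if (has_jargon) {
    jargon_templates <- c(
      outcome = "The main outcome we measured was relief of symptoms.",
      literature = "We reviewed the published literature on this topic.",
      `case series` = "Evidence from one case series was also considered.",
      efficacy = paste0("The efficacy of ", int_l,
                        " was assessed in each study."),
      `effect size` = "The effect size for pain relief was large."
    )
    n_terms <- pick(1:2)
    terms <- sample(names(jargon_templates), n_terms)
    if (hard()) {
      terms <- "efficacy"
      sentences_j <- "The efficacies of the treatments were compared."
    } else {
      sentences_j <- unname(jargon_templates[terms])
    }
    jargon_label <- sort(terms)
    results <- c(results, sentences_j)
  }

  # --- assemble body ---------------------------------------------------
  search_block <- c(date_sentence, leak)
  sections <- list(
    list(heading = "Review question", prose = question),
    list(heading = "Background", prose = background),
    list(heading = "Study characteristics", prose = c(search_block,
                                                      characteristics)),
    list(heading = "Key results", prose = results),
    list(heading = "Quality of evidence", prose = quality_prose)
  )
  heading_forms <- if (noisy) {
    c("Review question" = pick(c("Review question", "Review questions:")),
      "Background" = pick(c("Background", "BACKGROUND")),
      "Study characteristics" = pick(c("Study characteristics",
                                       "Study Characteristics:")),
      "Key results" = pick(c("Key results", "Key results:")),
      "Quality of evidence" = pick(c("Quality of evidence",
                                     "Quality of the evidence")))
  } else {
    setNames(pls_lexicons()$recommended_headings,
             pls_lexicons()$recommended_headings)
  }
  present <- character(0)
  if (structured) {
    canon <- map_chr(sections, "heading")
    present <- if (missing < 5L) {
      sort(sample(canon, 5L - missing))
    } else {
      character(0)
    }
  }
  lines <- character(0)
  for (sec in sections) {
    prose <- sec$prose[!map_lgl(sec$prose, is.null)]
    if (length(prose) == 0) next
    if (structured && sec$heading %in% present) {
      lines <- c(lines, paste0("## ", heading_forms[[sec$heading]]))
    }
    lines <- c(lines, paste(prose, collapse = " "))
  }
  if (structured && missing == 5L) {
    # structured, but with none of the recommended headings
    lines <- c("## Aim", lines[1], "## Findings", lines[-1])
  }
  body <- paste(lines, collapse = "\n")

  mean_gap <- cfg$word_mean - cfg$word_min
  scale <- cfg$word_sd^2 / mean_gap
  shape <- mean_gap / scale
  target <- cfg$word_min + round(rgamma(1, shape = shape, scale = scale))
  wc <- count_words(body)
  if (wc < target - 5L) {
    extra <- pad_sentences(character(0), wc, target)
    body <- paste(c(body, paste(extra, collapse = " ")), collapse = "\n")
  }
  wc_final <- count_words(body)

  pub_year <- 2013L + (month + 2L) %/% 12L
  pub_month <- (month + 2L) %% 12L + 1L

  doc <- tibble(
    doc_id = sprintf("PLS%05d", i),
    review_title = review_title,
    pls_title = pls_title,
    body = body,
    pub_month = pub_month,
    pub_year = pub_year,
    review_group = group,
    is_empty_review = empty
  )
  label <- tibble(
    doc_id = doc$doc_id,
    is_empty_review = empty,
    item1_title_same = item1_same,
    item2_word_count = wc_final,
    item3_jargon = list(jargon_label),
    item4_structured = structured,
    item5_subtitles_recommended = if (structured) missing == 0L else NA,
    item6_missing_headings = if (structured) missing else NA_integer_,
    item7_search_date = tier,
    item8_strategy = list(leak_label),
    item9_population = pop,
    item10_studies_stated = n_stud,
    item11_participants_stated = n_part,
    item12_stats = if (empty) list(NULL) else list(stats_label),
    item13_quality = quality,
    item14_grade = grade
  )
  list(doc = doc, label = label)
}

#' Hand-authored edge-case fixtures with fully specified expectations
#'
#' Each fixture returns a one-row corpus tibble plus the expected
#' [assess_pls()] assessment and the expected [score_assessments()] result
#' under the default scheme. The bundled set covers the extremes a real
#' corpus exhibits: a three-sentence 46-word minimal summary, the summary of
#' an empty review (13-point context), heading spellings that only match
#' after normalization, and a narrative-but-otherwise-perfect summary (the
#' 12/19 case).
#'
#' @param name One of `"minimal_three_sentence"`, `"empty_review_basic"`,
#'   `"heading_variants"`, `"narrative_perfect"`.
#' @return A list with `document`, `assessment` and `result`.
#' @examples
#' fx <- make_fixture("empty_review_basic")
#' fx$result$max_points  # 13
#' @export
make_fixture <- function(name = c("minimal_three_sentence",
                                  "empty_review_basic",
                                  "heading_variants",
                                  "narrative_perfect")) {
  name <- match.arg(name)
  fx <- switch(name,
    minimal_three_sentence = fixture_minimal(),
    empty_review_basic = fixture_empty(),
    heading_variants = fixture_headings(),
    narrative_perfect = fixture_narrative_perfect()
  )
  fx$result <- score_assessments(fx$assessment)
  fx
}

fixture_doc <- function(doc_id, review_title, pls_title, body,
                        pub_month = 6L, pub_year = 2014L,
                        review_group = "Fixture", is_empty_review = FALSE) {
  pls_corpus(tibble(
    doc_id = doc_id, review_title = review_title, pls_title = pls_title,
    body = body, pub_month = pub_month, pub_year = pub_year,
    review_group = review_group, is_empty_review = is_empty_review
  ))
}

fixture_assessment <- function(doc_id, is_empty_review, item1, item2,
                               item3 = character(0), item4 = FALSE,
                               item5 = NA, item6 = NA_integer_,
                               item7 = "none", item8 = character(0),
                               item9 = NA, item10 = NA, item11 = NA,
                               item12 = NULL, item13 = NA, item14 = NA) {
  tibble(
    doc_id = doc_id, is_empty_review = is_empty_review,
    item1_title_same = item1, item2_word_count = as.integer(item2),
    item3_jargon = list(item3), item3_ambiguous = list(character(0)),
    item4_structured = item4, item5_subtitles_recommended = item5,
    item6_missing_headings = as.integer(item6), item7_search_date = item7,
    item8_strategy = list(item8), item9_population = item9,
    item10_studies_stated = item10, item11_participants_stated = item11,
    item12_stats = list(item12), item13_quality = item13,
    item14_grade = item14
  )
}

# 46 words in three sentences: the shortest summary shape seen in practice
fixture_minimal <- function() {
  body <- paste(
    "This short summary presents what we found when we reviewed honey as a remedy for coughs.",
    "We found only limited evidence, and the benefit of honey remains uncertain.",
    "More careful and well planned research is needed before any firm conclusions about this remedy can be drawn."
  )
  list(
    document = fixture_doc("FX_MIN", "Honey for acute cough in children",
                           "Honey for coughs", body),
    assessment = fixture_assessment(
      "FX_MIN", FALSE, item1 = FALSE, item2 = 46L,
      item9 = FALSE, item10 = FALSE, item11 = FALSE,
      item12 = character(0), item13 = FALSE, item14 = FALSE
    )
  )
}

fixture_empty <- function() {
  body <- paste(
    "## Review question",
    "Does treatment with antibiotics shorten a sore throat?",
    "## Background",
    "A sore throat is painful and common.",
    "## Study characteristics",
    "The evidence is current to June 2014. We found no studies that met the inclusion criteria.",
    "## Quality of evidence",
    "No evidence was available for this question.",
    "## Key results",
    "No conclusions could be reached.",
    sep = "\n"
  )
  list(
    document = fixture_doc("FX_EMPTY", "Antibiotics for sore throat",
                           "Do antibiotics help sore throat?", body,
                           is_empty_review = TRUE),
    assessment = fixture_assessment(
      "FX_EMPTY", TRUE, item1 = FALSE, item2 = 53L,
      item4 = TRUE, item5 = TRUE, item6 = 0L, item7 = "month_and_year"
    )
  )
}

# colon, case and wording variants of all five recommended headings
fixture_headings <- function() {
  body <- paste(
    "## Review questions:",
    "Can exercise therapy reduce low back pain?",
    "## BACKGROUND",
    "Low back pain is very common in working life.",
    "## Study Characteristics:",
    "We searched for studies up to 14 March 2014. We included 12 studies with 1046 participants.",
    "## Key results",
    "Exercise therapy reduced pain more than no treatment.",
    "## Quality of the evidence",
    "The quality of the evidence was moderate.",
    sep = "\n"
  )
  list(
    document = fixture_doc("FX_HEAD", "Exercise therapy for chronic low back pain",
                           "Can exercise help long-lasting low back pain?",
                           body),
    assessment = fixture_assessment(
      "FX_HEAD", FALSE, item1 = FALSE, item2 = 58L,
      item4 = TRUE, item5 = TRUE, item6 = 0L, item7 = "month_and_year",
      item9 = FALSE, item10 = TRUE, item11 = TRUE,
      item12 = character(0), item13 = TRUE, item14 = FALSE
    )
  )
}

# narrative but otherwise ideal: loses exactly items 4 (1), 5 (1) and 6 (5)
fixture_narrative_perfect <- function() {
  core <- paste(
    "We wanted to find out whether massage helps with knee osteoarthritis.",
    "The evidence is current to June 2014.",
    "We included adults aged over 65 with knee osteoarthritis.",
    "We included 12 studies with 2317 participants in total.",
    "Those given the treatment generally felt better.",
    "We assessed the quality of the evidence using the GRADE approach."
  )
  n_core <- count_words(core)
  target <- 420L
  body <- paste(core, flex_sentence(target - n_core))
  list(
    document = fixture_doc("FX_NARR", "Massage for knee osteoarthritis",
                           "Does massage help with knee osteoarthritis?",
                           body),
    assessment = fixture_assessment(
      "FX_NARR", FALSE, item1 = FALSE, item2 = target,
      item7 = "month_and_year",
      item9 = TRUE, item10 = TRUE, item11 = TRUE,
      item12 = character(0), item13 = TRUE, item14 = TRUE
    )
  )
}
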