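---
title: "Measuring PLEACS adherence in plain language summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring PLEACS adherence in plain language summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plscore)
library(dplyr)
```

## The measurement problem

Every Cochrane intervention review carries a plain language summary (PLS),
a short consumer-facing account of the question, the evidence and the
result. The PLEACS reporting standards prescribe what such a summary should
contain; `plscore` operationalizes the *measurable* part of that checklist
as fourteen items that can be assessed from the summary text and its
metadata alone, and turns each summary into a point score, a percentage and
an adherence band.

The fourteen items, with their measurement type:

| # | Item | Type |
|---|------|------|
| 1 | PLS title identical to the review title (should be *restated*, so identity is a violation) | binary, reverse |
| 2 | Word count (adherent inside 400–700 words) | count |
| 3 | Technical jargon present (outcome, literature, case series, efficacy, effect size) | term list, reverse |
| 4 | Structured (contains headings) vs narrative | binary |
| 5 | If structured: all five recommended headings present | binary, conditional |
| 6 | If structured: how many of the five recommended headings are missing | graded 0–5, conditional |
| 7 | Search date given (month + year > year only > none) | tiered |
| 8 | Search-strategy detail leaked (database names, search syntax) | pattern list, reverse |
| 9 | Population details given | binary |
| 10 | Number of included studies stated | binary |
| 11 | Number of participants stated | binary |
| 12 | Complex statistics used without explanation | pattern list, reverse |
| 13 | Quality of the evidence addressed | binary |
| 14 | Quality addressed via the GRADE system | binary |

Two applicability rules cut across the items. For the PLS of an **empty
review** (a review that included no studies — a metadata flag, never
inferred from the text) items 9–14 are not collected. For a **narrative**
summary, items 5–6 are undefined. Additionally, a GRADE mention (item 14)
implies that quality is addressed (item 13). Assessments violating these
rules are rejected, and the generator never emits them.

## The scoring model

The default scheme awards one point per binary item, with the reverse items
(1, 3, 8, 12) awarding their point when the offending element is *absent*;
item 6 is graded as $5 - \text{missing headings}$; item 7 is tiered
(month + year = 2, year only = 1, none = 0). Not-applicable items
contribute zero points against a **fixed per-context maximum**:

$$
\text{adherence} = \frac{\sum_i \text{points}_i}{M} \times 100\,\%,
\qquad M = \begin{cases} 19 & \text{review with included studies}\\
13 & \text{empty review}\end{cases}
$$

The 19/13 ceilings are the published constants of the scoring system;
`verify_scheme()` re-derives them by exhaustively enumerating every
extreme-value combination of the fourteen items (coupling the structure and
empty-review rules), so any rescaled scheme can be checked against its own
declared constants:

```{r}
verify_scheme(default_scheme())
```

The exact point table of the original instrument is not reproduced in the
article text; the default scheme here is the *minimal* assignment consistent
with every published constraint — fourteen items, reverse set {1, 3, 8, 12},
maxima 19 and 13, a two-tier search-date item, a 0–5 graded heading item.
The scheme is a plain configurable object (`new_pls_scheme()`,
`read_scheme()`/`write_scheme()`), so a different point table can be dropped
in without touching the pipeline.

Percentages are rounded half-up to integers for display and banded as
0–25, 26–50, 51–75, 76–100. The published results label the top band both
"75–100 %" and "76–100 %"; we treat the boundary as (75, 100] on the
rounded percentage, which reproduces both labels' behaviour on integer
displays.

## Detector design and tunables

The detectors are deliberately rule-based: the aim is a deterministic,
auditable operationalization, not a trained classifier.

* **Text convention.** A corpus is JSON-lines; heading lines inside a body
  start with `"## "`. The original study assessed rendered web pages where
  headings are typographically marked; the marker is the plain-text
  equivalent. An optional heuristic (`heading_heuristic = TRUE`) treats
  short title-case lines without terminal punctuation as headings for
  unmarked text.
* **Titles** (item 1) are compared after case folding, whitespace collapse
  and stripping terminal punctuation.
* **Jargon** (item 3) is matched whole-word, case-insensitively, with
  optional plural stemming (a trailing *s*/*es*). Words whose medical
  meaning merely *differs* from everyday usage (local, blinding, control,
  practice) form a separate **ambiguous tier**: they are reported but
  excluded from scoring unless `include_ambiguous = TRUE`, because the
  standards list them as caveats rather than forbidden words.
* **Headings** (items 4–6) are normalized (case, trailing colon) and
  matched against the recommended five, tolerating the common variants
  "Review questions" and "Quality of the evidence".
* **Search date** (item 7) requires a date expression in the *same
  sentence* as a search cue ("searched", "current to", "up to date"),
  using a `". "` sentence-boundary heuristic. This prevents unrelated
  years — trial publication dates, say — from counting as a search date.
* **Strategy leakage** (item 8) matches database proper names
  (case-sensitively: MEDLINE, EMBASE, CENTRAL, ...), quoted boolean search
  strings, `MeSH`, and explicit search-term lists.
* **Counts** (items 10–11) match numerals (with thousands separators) or
  spelled-out numbers up to twenty, within two tokens of a kind-specific
  noun. "We found no trials" counts as a stated study count of zero — it
  conveys the number — but this is configurable
  (`count_none_as_stated`).
* **Statistics** (item 12) match notation classes (odds/risk/hazard
  ratios, SMD, MD, confidence intervals), each requiring a numeric value in
  the same clause. A match is treated as *explained* when an explanation
  cue ("this means", "in other words", "out of 1000", ...) starts within a
  window of **12 tokens** after it. The standards give no operational rule
  for "explained"; the window is our construction and is a tunable
  (`suppression_window`).
* **Quality** (items 13–14) phrases are matched in prose only: a bare
  "Quality of evidence" heading is structure (items 4–6), not content.
  GRADE must appear as a capitalized whole word.
* **English only**, as in the original study; month names and number words
  are English.

## What the synthetic generator emulates

No PLS corpus is redistributed with the package, so validation runs on a
generator whose defaults emulate the published corpus conditions: 176/1738
empty reviews, per-item adherence rates set to the published adherence
table (64 % restated titles, 36 % structured, 99 % leak-free, 0.7 % GRADE,
...), the published missing-heading distribution among structured
summaries, search-date tier frequencies, a shifted-gamma word-count
distribution with mean 319 and minimum 46, publication months spanning
the 23 months from March 2013 to January 2015, six review groups with
adherence offsets spanning ±0.12, and an optional linear
adherence-probability trend per month applied to the eight unit-weight
Bernoulli items (1, 3, 8, 9, 10, 11, 12, 13). One published cell —
"year only: 20 (11 %)" — is internally inconsistent (20/1738 ≈ 1.1 %);
we use the count, and all report percentages are computed from counts.

Item 2 has no independent rate: word counts are drawn from the word-count
distribution and the item's truth follows from the realized count, exactly
as in real data. Bodies are padded with neutral filler sentences to within
five tokens of the drawn target.

Every document's drawn item values are emitted as **ground-truth labels**.
In *clean* mode each value is realized with phrasing the detectors are
guaranteed to recover, so label–assessment agreement is exactly 100 % —
this is what makes the extraction, scoring and aggregation layers testable
end to end. In *noisy* mode, benign paraphrase and heading variants are
mixed in, and a fixed 3 % of applicable realizations of items 3, 7, 9 and
10 use phrasing deliberately beyond the rules (inflections the stemmer
misses, a season instead of a month, unlisted population nouns,
hyphenated spelled numbers); per-item agreement then sits near 97 %.

Passing clean-mode tests therefore shows that the pipeline is *internally
coherent* — detectors invert the generator, scores computed from text equal
scores computed from truth, configured rates and trends are recovered
within sampling error. It does **not** show that the rules capture every
phrasing found in real summaries; noisy mode bounds that gap only for the
paraphrase families the generator knows about. Free-text paraphrase,
semantic jargon, and non-English text are out of scope by design.

## Numerical and procedural choices

* Publication time is indexed in months since March 2013 (the month the
  current standards took effect). Documents without a month are excluded
  from the trend by default; `impute_midyear = TRUE` assigns July instead.
* The trend is a per-document ordinary least-squares regression of
  adherence percentage on month index, with the Pearson correlation
  computed on the same pairs — not a regression on monthly means.
* Zero-variance adherence is flagged (`pearson_r = NA`) rather than
  fitted; a corpus published in a single month is a degenerate design and
  an error.
* Not-applicable items score zero against the fixed 19/13 denominators,
  because the instrument publishes fixed per-context ranges rather than
  per-document maxima.
* Item 2 awards binary in-range credit (400–700); the instrument's
  treatment of under- versus over-length summaries is not published, and a
  partial-credit rule can be configured via a custom scheme.
* Rounding for display and banding is half-up (`floor(x + 0.5)`), matching
  the integer percentages of the published table; unrounded values are kept
  in all machine output.

## Problem sizes used by the test-suite

The bundled checks run at sizes chosen to keep sampling error well inside
the asserted tolerances while remaining quick on a laptop: label-fidelity
and oracle-equivalence corpora of 500 documents, rate recovery at 1000
documents (three binomial standard errors), trend recovery at 800–1000
documents over the 23-month window, slope-coverage across 100 seeded
replicates, and property suites over 10,000 randomized assessments.

## Known limitations

* The rules encode canonical Cochrane phrasing; recall on arbitrary
  real-world phrasing is untested by construction (see above).
* The item-12 "explained" window and the item-9 qualifier list are
  heuristics; both are exposed as configuration for sensitivity analysis.
* The default point table is a reconstruction constrained by the published
  maxima and reverse set, not the original supplementary table; swap in
  the true table via `new_pls_scheme()` when it is available.
* Human checklist steps — duplicate extraction, discrepancy resolution,
  and the consistency item that requires reading the full review — are
  outside what text-only measurement can do and are deliberately not
  modelled.
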