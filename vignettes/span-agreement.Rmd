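---
title: "Measuring inter-rater agreement for span-level clinical annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inter-rater agreement for span-level clinical annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spanagree)
```

## The problem

Clinical phenotyping turns the free text of progress notes into computable
codes in two steps: a rater (human or machine) marks the text span of each
sign or symptom, and the span is then *normalized* — mapped to a concept in
an ontology and its machine-readable code (`"patient movements were
ataxic"` → concept *ataxia* → a UMLS-style CUI). Before trusting any
annotator, human or automated, one has to know how well two annotators
agree on the same notes. `spanagree` implements that measurement for
span-level annotation: it constructs the agreement units for a rater pair,
computes concordance (unadjusted agreement) and Cohen's Kappa
(chance-adjusted) for both the text-span and the category-label task,
assigns a seven-way span taxonomy, normalizes spans to concepts, and ships
a synthetic note/annotator generator so the whole chain can be exercised
and calibrated without access to protected health records.

## Agreement units and the two statistics

Notes are split into *screens* (one line of text, one annotation context).
For a rater pair (A, B), the denominator of both statistics is

> |A ∪ B| + null screens,

one unit per span in the union of the two raters' annotations (a span both
raters marked counts once) plus one unit per screen that neither rater
annotated. A screen that neither rater marked is an *agreement*: both
raters judged it free of signs and symptoms, and most screens in real
notes are of this kind, which is exactly why a chance-corrected statistic
is needed alongside raw percent agreement.

For the **text-span task**, each unit is rated `present` or `null` per
rater; for the **category-label task**, the rater's category label stands
in for `present`, so a span both raters marked but labeled differently
counts as a disagreement and an unmatched span disagrees with `null`. Both
tasks share the same denominator; the label task is strictly harder.

With `po` the fraction of agreeing units and `pe = Σ_c pA(c)·pB(c)` the
chance agreement from each rater's marginal rating frequencies over those
same units (Cohen's formulation),

* concordance = `100 · po` (percent),
* `κ = (po − pe) / (1 − pe)`.

Two degenerate cases are handled explicitly: an all-null corpus has
`po = pe = 1` and returns `κ = 1` with a warning (there is nothing to
disagree about), and `κ < 0` (worse than chance) is returned as computed.
With marginal-based `pe`, `pe = 1` forces `po = 1`, so the undefined
division cannot arise from real unit lists; the error branch exists as a
guard for hand-built inputs.

Span matching defaults to **exact offsets**: two raters agree on a span
only if they marked identical character ranges (0-based, half-open, in
code points). An `overlap` mode (greedy pairing by maximal character
overlap, leftmost-start tie-break) is available through `match_config()`
but off by default, because exact matching is the stricter and more
reproducible criterion and near-miss credit is a policy choice the user
should make deliberately.

## The category-label taxonomy

Spans carry one of seven labels: `unigram` … `tetragram` by token count,
`extended` (more than four tokens), `compound` (several concepts in one
span, e.g. *brisk ankle and knee reflex*), and `tabular` (the screen is
column-formatted, typically right/left body sides). `assign_category()`
applies them with priority **tabular > compound > token count**: compound
spans can exceed four tokens, so length cannot take precedence, and
tabular is a property of the screen layout rather than of the span text.
Two heuristics are configurable because the underlying conventions are
conventions, not rules of nature:

* *compound detection*: a coordinator (`and`, `or`, or a comma) strictly
  inside the span with at least one token on each side;
* *tabular detection*: at least two runs of two or more consecutive
  spaces, or both `right` and `left` appearing as words.

Hyphenated words count as one token by default (`visuo-spatial neglect`
is a bigram); hyphens are a known source of label disagreement, so the
behavior is a `labeling_config()` switch.

## Normalization

`build_lookup()` compiles a concept catalog (TSV: `concept_id`,
`preferred_label`, `code`, pipe-delimited `synonyms`) into a normalized
phrase table; `normalize_span()` tries an exact hit first and falls back
to a similarity search. The similarity is **character-trigram cosine**: it
is deterministic, dependency-free, and more than adequate for the
inflectional variants this step actually has to absorb (*ataxic* →
*ataxia* scores 0.625; unrelated strings score near 0). The scorer is an
argument, so a word-vector similarity can be plugged in without touching
the rest. The acceptance threshold defaults to 0.7 — high enough that
random surfaces stay unmapped, low enough for single-character inflections
— and raising it can only reduce the number of mapped spans. Ties break
to the lexicographically smallest `concept_id` so results are stable.

The shipped catalog (`inst/extdata/neuro_ontology_synthetic.tsv`) is a
~60-concept *synthetic* neurology catalog built for this package: it has
the structure of a real neuro-ontology lookup table (including the
*ataxia* / `C0004134` entry with synonym *ataxic*) but its other codes are
synthetic `C9xxxxxx` identifiers. A real catalog in the same TSV format
drops in via `read_concept_catalog()`.

Normalization is downstream of the agreement statistics: unmapped spans
are reported (method `"none"`) but never change κ or concordance.

## What the synthetic generator emulates

`generate_corpus()` produces what the statistics assume as input:

* **screen structure** — `n_notes × screens_per_note` one-line screens;
  defaults 5 × 125 = 625 screens, matching a realistic five-note
  annotation round;
* **sparse concepts** — each screen carries one annotatable sign/symptom
  with probability `concept_screen_fraction` (default 0.22, i.e. ~139
  concepts per 625 screens), so most screens are null screens;
* **negation** — a screen *without* a gold concept instead mentions a
  negated concept ("Denies …", "No … on review") with probability
  `negated_fraction` (default 0.08); these mentions are recorded so that
  annotating one can be penalized. Defining `negated_fraction` on the
  non-concept screens keeps `concept_screen_fraction` exactly the
  gold-span screen fraction, which the closed form below relies on;
* **span-length mix** — `category_mix` over the six non-tabular labels
  (defaults weighted toward unigrams/bigrams, as sign-symptom mentions
  are); `tabular_screen_fraction` (default 0.05) of concept screens use a
  right/left columnar layout;
* **one concept per concept screen** by default (`concepts_per_screen`
  raises it), again to keep the closed form exact.

Planted phrases come from the concept catalog, and each gold label is, by
construction, what `assign_category()` assigns — verified by test.

`simulate_annotator()` then models the disagreement sources that occur in
practice: per-category **sensitivity** (missed spans), **false positives**
(spurious 1–2-token spans per 100 screens), **boundary jitter** (one edge
moved by one token, which exact matching scores as disagreement), **label
confusion** (a row-stochastic 7×7 matrix), and a **negation error rate**.
The two stock profiles are calibration choices, not estimates from data:
`human_profile()` (sensitivity 0.92, 0.5 FP/100 screens, 2% jitter, 3%
label confusion, 2% negation errors) and `machine_profile()` (sensitivity
decreasing with span length, mean 0.80 — automated annotators degrade on
longer spans — 2 FP/100 screens, 5% jitter, 8% confusion, 5% negation
errors). They are chosen to reproduce the qualitative structure of a
human-vs-machine comparison — human–human κ above human–machine κ in
every replicate, with a span-task gap of roughly 0.1 — not any particular
published value.

In the zero-false-positive, zero-jitter, exact-match, one-concept-per-
screen regime every screen contributes exactly one unit, and the expected
concordance has the closed form

> `E[po] = (1 − f) + f·(sA·sB + (1 − sA)(1 − sB))`,

implemented in `expected_concordance()` with its preconditions enforced.
The test suite checks that the full simulate → build-units → score path
recovers this within ±0.02 at 5,000 screens; this parameter-recovery loop
is the package's strongest internal consistency check.

What the generator does **not** emulate: real clinical language (screens
are template sentences), abbreviation/jargon ambiguity, inter-note style
variation, correlated rater errors (simulated raters err independently;
real raters share training and blind spots, which inflates their mutual
agreement), and concept frequency distributions of any real ontology.
Passing tests therefore demonstrate the correctness and calibration of
the measurement machinery, not the agreement level of any particular
human cohort.

## Group comparison

`run_pipeline()` scores every rater pair per round and task, tags pairs
`human-human` / `human-machine`, and `summarize_agreement()` reports
mean ± sample SD per group, round, and pooled (SD is `NA` for a single
observation). Groups are compared with `anova_oneway()` — the classical
one-way between/within decomposition with the p-value from the upper F
tail — applied to **per-pair-round** values pooled across rounds (three
human-human and three human-machine pairs × three rounds = 9 + 9
observations, df = (1, 16)). Treating pair-rounds as replicates is a
choice: the observations within a round share a corpus, so they are not
fully independent, and the usual ANOVA caveats (normality, homogeneity,
independence) are inherited, not resolved. Degenerate inputs are explicit:
identical group means give F = 0, and zero within-group variance with
unequal means is an error rather than a silent `Inf`. No multiple-testing
correction is applied by default since only one planned comparison per
task/metric is run.

## Numerical and design notes

* Offsets are 0-based half-open everywhere and count code points;
  `length(surface) = end − start` holds for every accepted span.
* Within one rater and screen, spans must be non-overlapping (validation
  reports an `overlap` finding); one rater per annotation file.
* All randomness flows through R's RNG from explicit seeds; corpora,
  annotators and pipeline reports are bit-reproducible, and the pipeline
  derives per-round/per-rater seeds from its base seed so rounds are
  independent but replayable. Reports contain no timestamps, making
  repeated runs byte-identical.
* Test problem sizes are chosen so statistical assertions have comfortable
  margins at desk scale: 5,000 screens put the Monte-Carlo error of a
  concordance near 0.007 (so a ±0.02 assertion is a >2.5σ margin), and 20
  replicate studies of 3 × 625 screens make the human-vs-machine κ
  ordering essentially certain per replicate given the ~0.1 mean gap.

## Known limitations

* Exact-offset matching is harsh on boundary disagreements; the overlap
  mode softens it but the package deliberately takes no position on
  partial-credit weighting.
* The label task is scored on the same unit list as the span task
  (unmatched spans count as label disagreements), which couples the two
  tasks; conditioning label agreement on span agreement would be a
  different, also defensible, definition.
* Multi-rater coefficients (Fleiss, Krippendorff) are out of scope; the
  design is strictly pairwise.
* Trigram cosine similarity has no semantic knowledge: it maps
  inflections, not paraphrases ("double vision" will not reach
  "diplopia" without a synonym entry).
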