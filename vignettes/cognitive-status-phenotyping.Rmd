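---
title: "Semiautomated phenotyping of cognitive status: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiautomated phenotyping of cognitive status: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natkit)
```

## The problem and the approach

Cognitive impairment is systematically under-represented in structured EHR
data: clinicians record concerns in free text long before (and often
instead of) assigning a dementia diagnosis code or prescribing a dementia
medication. Purely code-based phenotyping therefore mislabels many impaired
patients as normal, and — equally important — mislabels patients whose
records are simply too thin to judge. `natkit` implements a semiautomated
workflow: automated extraction, keyword highlighting, note triage and a
rule-based label *suggestion* prepare an integrated view of one patient's
chart, and a human annotator makes the final call among three labels —
cognitively normal (CN), cognitively impaired (CI), and *undetermined* for
charts with insufficient information. The package also carries the
statistical toolkit used to evaluate such workflows (agreement, timing,
learning effects, cohort description) and a synthetic-EHR generator so that
every component is testable end to end without protected health data.

## Data model

A *chart bundle* is a directory of CSV tables (patients, notes, encounters,
medications, diagnoses, labs, imaging, refills) plus a plain-text manifest
naming the tables and the covered date range. Loading validates every row;
unparseable rows (malformed dates, missing patient ids, unknown encounter
statuses) go to a reject report rather than being silently dropped, because
in chart review a silently missing note changes the label. Duplicate note
ids are fatal rather than deduplicated: the right resolution for addenda
and copies is a data-curation decision we refuse to guess at.

Period filtering keeps records with `start ≤ date ≤ end`. Undated records —
current-medication entries and undated problem-list rows — are always
retained: they describe present state, not a dated event, and the current
medication list is precisely where dementia drugs are found.

Notes are segmented into *sequences*, contiguous character ranges of at
most `max_len` characters (default 512). Cuts are placed at sentence
boundaries when one is available within the limit, then at whitespace, then
hard. The concatenation of sequence texts reconstructs the note exactly,
and offsets are 0-based half-open, so every highlight has one unambiguous
placement. The 512-character default approximates the length of the short
passages a reviewer reads at a glance while staying independent of any
particular tokenizer; input text is treated as the caller supplies it
(UTF-8; callers wanting canonical offsets should NFC-normalise upstream).

## Lexicon matching

The lexicon is a CSV of regular expressions, each tagged with a category
(`cognition` or `adl`) and a polarity (`impaired` or `intact`). Matching is
case-insensitive, per-entry leftmost-longest and non-overlapping within an
entry (POSIX semantics), so results are deterministic and independent of
entry order. The package ships a default lexicon reconstructed from the
kinds of phrases that decide adjudications ("memory loss", "cognitive
decline", "memory … intact", "good fund of knowledge", ADL independence and
dependence phrasing); it is a documented working fixture, and studies are
expected to supply their own curated list via `read_lexicon()`.

Rendering wraps matched regions in `<mark>` tags keyed by category, with
polarity carried as a data attribute. Overlapping spans of the same
category are merged (the earliest-starting, longest span decides the
polarity of each character); regions covered by both categories nest with
the cognition tag outermost. The renderer is lossless by construction —
stripping tags restores the text byte for byte — which the reports rely on.
No negation-scope parsing is attempted: a phrase like "no cognitive
concerns" will match an impaired pattern, and surfacing both readings to
the human reviewer is the intended behaviour of a highlighting tool.

## Structured features

The engineered features follow the standard dementia work-up:

* **Medications** — stem-substring match on galantamine, donepezil,
  rivastigmine, memantine, catching brand/strength variants.
* **Diagnosis codes** — after normalisation (dots removed, upper-cased):
  ICD-9 prefixes 290, 294, 331 and the *exact* code 780.93; ICD-10 prefixes
  G30 and G31. 780.93 is deliberately not treated as a 780.9X family — the
  neighbouring 780.9X codes are unrelated symptoms.
* **Laboratories** — a configurable panel defaulting to vitamin B12,
  folate and TSH name variants; values are surfaced, never interpreted.
* **Utilization** — counts of no-shows, cancellations and refill requests
  relative to *all* scheduled encounters (completed + no-show + cancelled).
  With zero encounters the fractions carry an undefined flag rather than a
  fabricated zero.

## Triage and ranking

Classification is a contract, not a model: any `function(text) ->
(p_CI, p_noCI, p_neither)` with a normalised triple can be plugged in, so a
trained sequence classifier can replace the default without touching the
pipeline. The shipped baseline scores a sequence from its cognition keyword
counts — scores `(2·c_imp, 2·c_int, 1)` passed through a softmax — which is
deterministic, transparent, and sufficient to drive the ranking behaviour
on planted-keyword data. The weights mean one impaired keyword clears the
neither-bias (score 2 vs 1) and evidence accumulates multiplicatively in
probability space; they are tunable arguments, not magic constants.

A note's class is CI if any of its sequences predicted CI, else no-CI if
any predicted no-CI, else neither; its score is the maximum sequence
`p_CI`. Ranking places CI notes first, then sorts by descending score,
then by *later date first* — mirroring the latest-evidence adjudication
rule — then by note id for a stable total order. Ties in the probability
triple resolve CI > no-CI > neither, the conservative direction for a
screening display.

## Label suggestion

`suggest_label()` formalises the adjudication guideline as an ordered rule
list: (1) any dementia ICD code or medication ⇒ CI; (2) conflicting
impaired and intact cognition keywords ⇒ the latest-dated evidence decides,
with date ties resolved to impaired (conservative); (3) impaired only ⇒ CI;
(4) intact only ⇒ CN; (5) no evidence on a sparse chart (fewer than 3
notes, configurable) ⇒ undetermined; (6) otherwise CN on implicit evidence.
The conflict rule must be evaluated before the impaired-only rule —
otherwise a transient early concern would permanently override a later
normal evaluation, which is exactly the failure mode an integrated
date-aware view is meant to fix. The sparse-chart threshold of 3 notes is a
design choice (the guideline gives no numeric criterion): one or two notes
rarely contain the multisystem assessment needed for even implicit
evidence of normalcy. The suggestion always carries its rationale and is
never auto-saved; the human label is the product.

## Evaluation statistics

**Cohen's κ** is computed unweighted from the full contingency table:
`po = Σ diag / n`, `pe = Σ row·col / n²`, `κ = (po − pe)/(1 − pe)`,
undefined (flagged, not an error) when both raters use a single identical
category. Helpers implement the two preprocessing steps used in workflow
comparisons: removing pairs the tool side labelled undetermined (these
patients cannot be compared against a forced-choice external label), and
collapsing 5-class ordinal adjudications (normal … dementia) to CN/CI with
everything-not-normal ⇒ CI.

**Paired timing comparison.** Differences are `a − b`; zero differences are
dropped (the classical signed-rank convention, not Pratt's — the commonest
reading of "paired samples Wilcoxon test"), absolute differences are ranked
with average ranks for ties, and `W` is the positive-rank sum. For up to 25
nonzero pairs the two-sided p-value is exact: the full `2^n`
sign-assignment null is computed by convolution over doubled ranks (so
half-integer average ranks stay on an integer lattice), and
`p = min(1, 2·min(P(W ≤ w), P(W ≥ w)))`. Beyond 25 pairs a normal
approximation with tie correction and continuity correction is used; 25 is
comfortably inside the regime where exact computation is instant and the
approximation is already accurate. Because the mean/SD of differences can
reasonably be reported with or without zero pairs, the summary uses all
pairs (zeros included) and reports the dropped-zero count alongside.
Ratio summaries (median, min, max of `a/b`) require positive times.

**Learning effect.** An annotator's chronologically ordered durations are
split at the midpoint (odd counts put the extra patient in the first half)
and compared with a two-sided rank-sum test; identical constant halves
report p = 1.

**Demographics.** Table cells are `count (percent)` with percents computed
against the full cohort size — missing values reduce numerators only, never
the denominator, which is the only convention that reproduces printed cells
such as 160/527 → 30.4 — and rounded half-up to one decimal (base R's
round-half-even would render 62.5 as 62). The structured-dementia row
counts patients with a dementia ICD code *or* medication, reading the
conventional "code and medication" row title as naming the two evidence
sources rather than their conjunction.

## The synthetic cohort generator

`generate_cohort()` plants a ground-truth label per patient —
CI / undetermined / CN with marginal probabilities (0.3, 0.2, 0.5) by
default — and generates a chart consistent with it from clinical-sounding
sentence templates with keyword slots. Template text (rather than
free-form generation) is what makes every emission probability a testable
parameter. Defaults, chosen once as a realistic desk-scale condition:

* Labeled patients carry `5 + Poisson(5)` notes; undetermined patients 1–2
  evidence-free notes (below the sparsity threshold) and minimal
  utilization, emulating the thin-record patients that dominate
  undetermined fractions in mixed-age cohorts (≈ 20%).
* CI patients emit an impaired-cognition sentence per note with
  probability 0.6 — documented concerns recur across encounters once
  present — and carry a dementia ICD code with probability 0.5 and a
  dementia medication with probability 0.4; CN leak rates for all three
  are 0.01, representing coding noise.
* CN patients emit intact-cognition sentences at 0.35 per note, and 5% of
  them are *confounders*: an early transient impaired mention followed by
  a later explicitly intact note, the case the latest-evidence rule
  exists for.
* Two age/period templates: an elderly cohort (age ~ N(78.8, 7.4), fixed
  two-year window) and a mixed-age cohort (age ~ N(52.6, 15), two-year
  look-back window).
* Timing studies draw tool times from a log-normal (meanlog log 1.2,
  sdlog 0.4) and set manual = tool × speedup × exp(N(0, 0.5)), default
  speedup 2.2.

A single integer seed drives one root generator; the caller's RNG state is
saved and restored, and regeneration is byte-identical. Ground-truth labels
are returned separately and never written into the bundle, so no feature
can leak the answer.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: negated and hedged language ("denies memory
loss"), misspellings and OCR noise, copy-forward duplication, multi-problem
notes where cognition is incidental, and realistic correlation between
utilization and cognitive status. Synthetic recovery rates (suggestion
accuracy ≈ 0.97 at n = 500) are a correctness check of the pipeline against
its own planted structure, not a clinical performance estimate.

## Numerical and degenerate-input choices

Empty inputs return empty, typed results (empty note → zero sequences;
empty cohort summary and zero-pair κ are errors, since they have no
meaningful value). Fractions with zero denominators carry undefined flags.
κ with `pe = 1` is flagged undefined rather than NaN. All ranking and
assignment tie-breaks are total and documented, so every output is a
deterministic function of its inputs; no pipeline output embeds a
timestamp, which makes rerun-identity testable byte for byte. Problem sizes
used in the shipped test suite (cohorts of 500 for recovery properties,
1,000 replicates for oracle-equivalence and calibration loops) were chosen
as the smallest sizes at which the binomial confidence intervals involved
are informative.

## Known limitations

* Pattern-based matching only: no negation scope, no learned NER; the
  design assumes a human reads the highlights in context.
* The baseline classifier is a transparent stand-in; real deployments
  should plug in a trained sequence model through the classifier contract.
* Flat-file sessions are single-user; there is no authentication or
  concurrent-write handling.
* The statistics layer covers two-rater agreement only (no multi-rater
  generalisations, no κ confidence intervals).
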