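---
title: "Classifying registered clinical trials to GBD disease categories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying registered clinical trials to GBD disease categories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbdtrials)
```

## The problem

Trial registries require a free-text description of the health condition
studied plus a public and a scientific title, but no coded disease field.
Comparing research activity against the burden of disease therefore needs
a classifier from noisy free text to a burden taxonomy — here, a grouping
of the Global Burden of Diseases (GBD) 2010 cause list whose categories
are defined by sets of ICD-10 codes. `gbdtrials` implements such a
classifier as a chain of deterministic projections between knowledge
representations, plus the evaluation machinery to measure how well it
agrees with expert manual classification.

The design is knowledge-based rather than statistical on purpose: every
classification decomposes into auditable pathways
(field → concept → ICD-10 code → category), no training data is needed,
and the behavior is stable as registries grow.

## ICD-10 codes, blocks, and the grouping model

A code is a letter, a two-digit major, and an optional one-decimal minor
(`M16`, `M16.9`). The total order is by letter, major, then minor with the
bare code ranked immediately before its `.0` extension. A block
(`F30-F39.9`) denotes the contiguous range between its endpoints.

Block expansion enumerates the *syntactic grid*: every three-character
code and its ten decimal extensions between the endpoints, clipped
exactly. There is no dependence on an official tabular list of valid
codes — such lists are licensed, change by revision, and the downstream
projection intersects with the codes a grouping actually maps, so
syntactically valid but unused codes are harmless. Two consequences of
the clipping rule are worth noting: a block ending at a bare code
(`…-F39`) stops at `F39` itself, while `…-F39.9` covers all of F39's
extensions; `F30-F39.9` expands to exactly 110 codes. Hyphen, en-dash and
em-dash are normalized before parsing because registry and publication
exports disagree on the separator.

A grouping (`load_grouping()`, or the packaged `gbd28_grouping()`) is a
set of categories, each defined by code/block specs, with a residual flag.
Validation enforces mutual exclusivity: no four-character code may be
claimed by two non-residual categories. Residual categories ("Other …"
catch-alls) are loadable for bookkeeping but are never assignable —
they are deliberately excluded because they are uninformative for mapping
research to needs.

The shipped 28-class grouping reproduces the *structure* of the published
28-category consensus grouping (28 assignable + 2 excluded residual
categories). Its ICD-10 assignments are this package's own curation from
the named constituent causes of each category: the authoritative
ICD-10↔GBD table is external and not redistributable. Analyses that need
a specific official mapping should load it as a grouping TSV; everything
downstream is grouping-agnostic.

## The unique-inclusion projection rule

`project_code()` assigns a code to a category only when the code is
totally included in a unique non-residual category:

* a four-character code uses its own mapping, falling back to its
  three-character parent's;
* a three-character code is assigned only when the code and all of its
  mapped extensions agree on one category. The perinatal-infection code
  P37 is the canonical counterexample: with P37.0 under tuberculosis and
  P37.3 under neglected tropical diseases, `P37` projects to nothing.

The parent fallback exists because real groupings mix granularities:
without it, every four-character code under a block stated only at
three-character level would dangle. Blocks project as the union of their
constituent codes' projections (`project_spec()`), restricted to codes
the grouping knows about.

## Concept recognition and its surrogates

The annotator is an exact leftmost-longest dictionary matcher over
normalized tokens (lowercase, punctuation to spaces). At each position the
longest n-gram equal to a lexicon term with at least one
disorder-semantic-type concept wins; each such span yields one annotation
per qualifying concept. Spans are 0-based half-open character intervals
into the original text, so every annotation can be sliced back out for
audit.

Three deliberate simplifications relative to full-scale biomedical
concept recognizers:

* **No fuzzy or partial matching.** Exact matching keeps false-positive
  behavior auditable; misspelled terms are simply missed (the synthetic
  noise experiments quantify exactly this degradation). Fuzziness is an
  extension point, not a v1 feature.
* **Word-sense disambiguation surrogate.** When one span matches several
  concepts and `wsd = TRUE`, the concept whose preferred name has the
  highest normalized Levenshtein similarity to the matched text is kept,
  ties broken by smallest concept id. This is deterministic and
  reproducible, unlike a remote disambiguation service, and preserves the
  property the pipeline needs: with WSD the annotation set is a
  per-span-pruned subset of the without-WSD set.
* **External annotations.** Output of any other recognizer can be
  ingested via `read_annotations()` (validated JSON), bypassing the
  built-in matcher entirely — the downstream stages only need
  (field, concept) pairs.

The disorder filter defaults to the conventional disorders semantic
group (`default_disorder_types()`): disease/syndrome, neoplastic process,
mental dysfunction, injury, congenital and acquired abnormality,
pathologic function, sign/symptom. It is a plain character vector and can
be replaced per lexicon.

## Concept → ICD-10: the Restrict-to surrogate

`restrict_to_icd10()` returns a concept's own crosswalk entries; only a
concept with none ascends the hierarchy breadth-first and returns the
union of entries found at the first productive depth. Restricting the
fallback to ancestors (no lateral hops) and cutting at the shallowest
depth is the minimal deterministic reading of restrict-style
terminology projection; it is monotone in the crosswalk (adding a direct
entry can only tighten the result) and cheap to reason about in tests.

Expert enrichment is consulted per concept, strictly after the automatic
route: a concept with at least one automatic category never uses its
enrichment entry. This ordering is load-bearing (it is what makes
enrichment a fallback rather than an override) and is pinned by a test.

## Prioritization

Given all pathways for a trial:

1. **Field priority** (optional): if any pathway issues from the
   health-condition field, keep only those; otherwise fall back to
   title-derived pathways. The fallback matters — condition fields are
   frequently empty or uninformative, and titles are the designed
   recovery route.
2. **Multiplicity**: score each candidate category by its distinct
   (concept, code) supports; if any category reaches 2, drop the
   singletons. The threshold-at-2 rule is this package's concrete
   reading of "consistently supported beats isolated"; it lives behind
   `prioritize()` alone so alternative rules can be swapped in.

An empty survivor set is the "No GBD" outcome — the correct answer both
for residual-category conditions and for topics outside the taxonomy
(e.g. pain management), and an inherent weak point since any single
spurious concept can block it.

The three switches (WSD × enrichment × field priority) give the 8
variants of `classifier_variants()`, all of which are exercised by the
test suite on the same fixtures.

## Evaluation choices

* Exact matching compares predicted and gold category *sets*; both empty
  counts as a hit. Strata are defined by the gold label (one category /
  two or more / none) so the denominator of each stratum is
  classifier-independent.
* Per-category metrics are one-vs-rest; multi-label trials are positive
  for each of their categories; "No GBD" is scored as its own
  pseudo-category.
* Proportion CIs use the Wilson score interval (95%): it is asymmetric,
  respects [0, 1], and behaves at the boundary counts (0/n, n/n) that
  sparse categories produce. Likelihood-ratio CIs use the standard
  log-ratio normal approximation.
* Metrics with zero denominators (a category absent from gold, a perfect
  specificity making LR+ divide by zero) are reported as absent (`NA`,
  printed "-"), never coerced to 0 or 100.
* Weighted averages weight each category's sensitivity/specificity by its
  gold-positive count, including "No GBD"; categories with undefined
  values are excluded from that average. Likelihood ratios are computed
  from counts, not from rounded printed percentages, so a recomputation
  from rounded Sen/Spe may differ in the last digit.

## The synthetic-data generator

`generate_bundle()` builds a fully self-consistent world: category *i*
owns ICD-10 letter *i* entirely; concept *j* of category *i* has one
primary disease name, one synonym, and a crosswalk to `<letter><j>.0`;
trial texts are templated from those names. Because every automatic
pathway lands in its own category by construction, a clean corpus is
classifiable with 100% exact matching by every variant — that invariant
is what makes the generator a usable oracle for pipeline regressions.
Gold labels are fixed at generation time and never re-derived.

Controlled noise emulates the documented data-quality problems of
registry records: empty condition fields (term only in titles),
uninformative condition entries, healthy-volunteer trials (gold: no
category), ambiguous terms registered under two concepts in different
categories (exercising WSD and the multiplicity rule), multi-label
trials, and post-hoc perturbation (`perturb()`: seeded one-character
typos and synonym swaps, labels untouched).

What the generator does **not** emulate: the abbreviation styles,
misspellings-with-structure, multilingual fragments and template
boilerplate of real ICTRP text, nor a realistic category-frequency
distribution. Passing tests on synthetic corpora therefore demonstrate
pipeline correctness, not real-world accuracy; in particular the
verbatim-name baseline is artificially strong here because synthetic
condition fields *are* exact lexicon terms, whereas on real registry
text a verbatim baseline falls far behind a concept-based classifier.

Default problem sizes in the tests and the acceptance script (500-trial
corpora, 1000 random blocks, 100 noise seeds at 12–20 trials each) were
chosen to exercise every rule at stable proportions while keeping a full
run in a few minutes on one core.

## Numerical and degenerate-input choices

All stages are deterministic: no randomness exists anywhere in the
classifier, ties are broken lexicographically (concept ids) or by
position (leftmost-longest), and category sets are returned sorted.
Degenerate inputs are first-class: empty text fields annotate to nothing,
an empty pathway set classifies as "No GBD", an empty enrichment table
disables enrichment de facto, a batch survives malformed records by
logging and skipping them, and evaluation refuses silently mismatched
trial-id sets.

## Known limitations

* Exact matching of terms means recall on real text is bounded by lexicon
  coverage and spelling; the matcher is English-only.
* The shipped grouping's ICD-10 assignments are a documented curation,
  not the official burden-study mapping; results at category boundaries
  (e.g. which anemias sit with nutritional deficiencies) depend on it.
* The multiplicity rule's support unit and threshold are one defensible
  choice among several; they are isolated behind `prioritize()`.
* "No GBD" detection is structurally hard for this family of classifiers:
  one spurious pathway suffices to assign a category. Expect lower
  sensitivity for that pseudo-category than for disease categories.
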