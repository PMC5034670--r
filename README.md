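# gbdtrials

Registered clinical trials describe the condition they study as free text,
not with a standardized disease taxonomy, which makes it impossible to
compare the global research effort against the global burden of disease
without manual labeling. `gbdtrials` implements a knowledge-based
classifier that maps the three required free-text fields of a registered
trial — the health condition, the public title and the scientific title —
to categories of the Global Burden of Diseases (GBD) 2010 cause list,
together with the evaluation framework needed to validate such a
classifier against a manually labeled gold standard.

It is intended for researchers in clinical-trial informatics and health
policy who want to map corpora of registry records (WHO ICTRP exports or
ClinicalTrials.gov study XML) onto a burden-of-disease taxonomy, audit how
each classification was reached, and quantify classification accuracy.

## Method

Classification proceeds in five stages, each traced as explicit
*pathways* (field → concept → ICD-10 code → GBD category):

1. **Concept recognition.** Each text field is normalized (lowercase,
   punctuation stripped) and scanned with a deterministic leftmost-longest
   dictionary matcher over a mini-metathesaurus bundle (concepts with
   semantic types, synonym terms, hierarchy, concept→ICD-10 crosswalk).
   Only concepts whose semantic types mark diseases or injuries are kept.
   Optional word-sense disambiguation keeps a single concept per text
   span (highest preferred-name similarity). Externally produced
   annotations can be ingested instead.
2. **Concept → ICD-10.** A Restrict-to-ICD10-style projection: a
   concept's own crosswalk entries, falling back to the shallowest
   ancestors in the concept hierarchy that carry any.
3. **ICD-10 → GBD category.** A code or code block is projected onto a
   category only if it is *totally included in a unique* non-residual
   category. A three-character code whose four-character extensions split
   across categories (e.g. P37, whose .0 is tuberculosis and .3 a
   neglected tropical disease) projects to nothing. Blocks such as
   `F30-F39.9` are split into their constituent codes and projected code
   by code.
4. **Expert enrichment (optional).** Concepts with no automatic pathway
   may be routed through a hand-curated concept→category table.
5. **Prioritization.** Pathways from the health-condition field take
   priority over title-derived ones (optional), and categories supported
   by at least two distinct (concept, code) pairs suppress
   singly-supported candidates when any such category exists. An empty
   final set means "No GBD".

The three switches — WSD, enrichment, field priority — define 8 classifier
variants. The evaluation layer computes exact matching (predicted set ==
gold set) overall and by gold stratum, one-vs-rest sensitivity (Sen),
specificity (Spe) and positive predictive value per category with Wilson
95% intervals, likelihood ratios LR+ = Sen/(1−Spe) and LR− = (1−Sen)/Spe
with log-normal intervals, and gold-count-weighted averages. A
verbatim-name baseline (a trial is classified to a category when one of
the category's defining disease names appears at word boundaries in its
text) provides the knowledge-free comparison point.

The package ships a 28-class GBD grouping (28 assignable categories plus
2 residual categories excluded from classification) and the defining
disease names of each category; the ICD-10 code assignments in
`inst/extdata/gbd28.tsv` are a curation written for this package, not a
licensed code list.

## Worked example

```r
library(gbdtrials)

grouping <- gbd28_grouping()
lexicon <- build_lexicon(
  concepts = data.frame(
    cui = c("C0409959", "C0029410"),
    preferred_name = c("Osteoarthritis, Knee", "Osteoarthritis of hip"),
    semantic_types = "T047"),
  terms = data.frame(
    cui = c("C0409959", "C0029410"),
    term = c("Knee Osteoarthritis", "Hip Osteoarthritis")),
  crosswalk = data.frame(
    cui = rep(c("C0409959", "C0029410"), each = 2),
    icd10_spec = rep(c("M16", "M16.9"), 2)))

trial <- trial_record("NCT0000001",
  condition = "Knee Osteoarthritis; Hip Osteoarthritis",
  public_title = "Osteoarthritis of hip and knee study",
  scientific_title = "A trial in patients with Knee Osteoarthritis")

classify_trial(trial, lexicon, grouping)
#> <classification NCT0000001> musculoskeletal
```

Both recognized concepts project through the hip-arthrosis codes M16 and
M16.9, every pathway lands in "Musculoskeletal disorders", and the
prioritization rules return that single category — under any of the 8
variants (`classifier_variants()`). A code with extensions split across
categories projects to nothing:

```r
project_code("M16.9", grouping)
#> [1] "musculoskeletal"
g <- build_grouping(c("tb", "ntd"), c("Tuberculosis", "Neglected tropical"),
                    c(FALSE, FALSE), c("P37.0", "P37.3"))
project_code("P37", g)
#> [1] NA
```

Synthetic corpora with gold labels for end-to-end testing:

```r
bundle <- generate_bundle(fixture_spec(n_trials = 500, n_categories = 8,
                                       p_multi_label = 0.1, seed = 2024))
res <- classify_batch(bundle$trials, bundle$lexicon, bundle$grouping)
exact_matching(res, bundle$gold)$overall$proportion
#> [1] 1
```

A command-line interface (`inst/cli/gbdtrials.R`) wraps classification,
evaluation, the baseline, corpus simulation and the 8-variant grid; see
the header of that script for usage.

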