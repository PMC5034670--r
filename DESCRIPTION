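Package: gbdtrials
Title: Knowledge-Based Classification of Registered Clinical Trials to
    Global Burden of Disease Categories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps the free-text health-condition and title fields of
    registered clinical trials (WHO ICTRP or ClinicalTrials.gov exports)
    to categories of the Global Burden of Diseases (GBD) 2010 cause list.
    The classifier recognizes disorder concepts in text with a
    deterministic dictionary matcher over a mini-metathesaurus bundle,
    projects concepts to ICD-10 codes (Restrict-to-ICD10 style, with
    hierarchy fallback), projects codes and code blocks onto GBD
    categories under a unique-inclusion rule, optionally applies an
    expert-enrichment table, and resolves the final multi-label
    classification with prioritization rules. Ships a 28-class GBD
    grouping, a verbatim disease-name baseline, a diagnostic-accuracy
    evaluation layer (exact matching, per-category sensitivity,
    specificity, predictive values and likelihood ratios with confidence
    intervals), and a seeded synthetic-corpus generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
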