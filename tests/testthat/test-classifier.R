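test_that("trial_record validates ids and fills missing fields", {
  tr <- trial_record(c("T1", "T2"), condition = c("asthma", NA))
  expect_equal(tr$condition, c("asthma", ""))
  expect_equal(tr$public_title, c("", ""))
  expect_error(trial_record(""), "non-empty")
})

test_that("the variant grid enumerates exactly eight configurations", {
  variants <- classifier_variants()
  expect_length(variants, 8L)
  settings <- unique(t(vapply(variants, unlist, logical(3))))
  expect_equal(nrow(settings), 8L)
})

test_that("field priority restricts to condition-derived candidates", {
  paths <- data.frame(
    trial_id = "T1",
    field = c("condition", "public_title"),
    cui = c("C1", "C2"), icd10 = c("A00", "B00"),
    category_id = c("catA", "catB"),
    via_enrichment = FALSE, stringsAsFactors = FALSE)
  expect_equal(prioritize(paths, classifier_config(field_priority = TRUE)),
               "catA")
  expect_setequal(prioritize(paths, classifier_config(field_priority = FALSE)),
                  c("catA", "catB"))
  # condition yields nothing: titles serve as fallback
  titles_only <- paths[paths$field != "condition", , drop = FALSE]
  expect_equal(prioritize(titles_only, classifier_config(field_priority = TRUE)),
               "catB")
})

test_that("the multiplicity rule drops singly-supported categories", {
  paths <- data.frame(
    trial_id = "T1", field = "condition",
    cui = c("C1", "C2", "C3", "C4"),
    icd10 = c("A00", "A01", "A02", "B00"),
    category_id = c("catA", "catA", "catA", "catB"),
    via_enrichment = FALSE, stringsAsFactors = FALSE)
  expect_equal(prioritize(paths), "catA")
  # all singletons: everything is kept
  single <- paths[c(1, 4), ]
  expect_setequal(prioritize(single), c("catA", "catB"))
  # duplicated (cui, icd10) support counts once
  dup <- paths[c(1, 1, 4), ]
  expect_setequal(prioritize(dup), c("catA", "catB"))
  expect_equal(prioritize(paths[0, ]), character(0))
})

test_that("the worked osteoarthritis example classifies under all variants", {
  lex <- fig1_lexicon()
  g <- gbd28_grouping()
  trial <- fig1_trial()
  for (name in names(classifier_variants())) {
    cl <- classify_trial(trial, lex, g, NULL, classifier_variants()[[name]])
    expect_equal(cl$categories, "musculoskeletal", label = name)
    expect_false(cl$no_gbd)
  }
})

test_that("trials without recognizable disorders are No GBD", {
  lex <- fig1_lexicon()
  g <- gbd28_grouping()
  empty <- trial_record("T1")
  cl <- classify_trial(empty, lex, g)
  expect_true(cl$no_gbd)
  expect_length(cl$categories, 0L)

  pain <- trial_record("T2", condition = "pain management")
  expect_true(classify_trial(pain, lex, g)$no_gbd)
})

test_that("classification is deterministic", {
  lex <- fig1_lexicon()
  g <- gbd28_grouping()
  trial <- fig1_trial()
  a <- classify_trial(trial, lex, g)
  b <- classify_trial(trial, lex, g)
  expect_identical(a$categories, b$categories)
  expect_identical(a$trace, b$trace)
})

test_that("classify_batch preserves order and survives bad records", {
  bundle <- generate_bundle(fixture_spec(n_trials = 10, seed = 3))
  res <- classify_batch(bundle$trials, bundle$lexicon, bundle$grouping)
  expect_length(res, 10L)
  expect_equal(vapply(res, function(x) x$trial_id, character(1)),
               bundle$trials$trial_id)
  expect_equal(nrow(attr(res, "skipped")), 0L)

  broken <- bundle$trials
  broken$trial_id[4] <- NA_character_  # malformed record
  expect_warning(res2 <- classify_batch(broken, bundle$lexicon,
                                        bundle$grouping), "skipping")
  expect_length(res2, 10L)
  expect_null(res2[[4]])
  expect_equal(nrow(attr(res2, "skipped")), 1L)
  expect_equal(vapply(res2[-4], function(x) x$trial_id, character(1)),
               bundle$trials$trial_id[-4])

  expect_length(classify_batch(bundle$trials[0, ], bundle$lexicon,
                               bundle$grouping), 0L)
})

test_that("externally supplied annotations replace the built-in matcher", {
  lex <- fig1_lexicon()
  g <- gbd28_grouping()
  trial <- trial_record("T1", condition = "some opaque wording")
  ann <- data.frame(field = "condition", start = 0L, end = 4L,
                    matched_text = "some", cui = "C0409959",
                    stringsAsFactors = FALSE)
  cl <- classify_trial(trial, lex, g, annotations = ann)
  expect_equal(cl$categories, "musculoskeletal")
})

test_that("the verbatim baseline matches names at word boundaries only", {
  names_idx <- list(malaria = "Malaria", asthma_cat = "Asthma",
                    musculoskeletal = c("Osteoarthritis", "Gout"))
  t1 <- trial_record("T1", condition = "Malaria prophylaxis trial")
  expect_equal(baseline_classify(t1, names_idx), "malaria")

  # substring inside a word must not match
  t2 <- trial_record("T2", condition = "antimalarial drug study")
  expect_length(baseline_classify(t2, names_idx), 0L)

  t3 <- trial_record("T3", condition = "Knee problems")
  expect_length(baseline_classify(t3, names_idx), 0L)

  # field selection: name present only in the scientific title
  t4 <- trial_record("T4", condition = "chronic wheeze",
                     scientific_title = "Asthma management study")
  expect_length(baseline_classify(t4, names_idx, fields = "condition"), 0L)
  expect_equal(baseline_classify(t4, names_idx,
                                 fields = "scientific_title"), "asthma_cat")
  expect_equal(baseline_classify(t4, names_idx), "asthma_cat")

  # multi-word names and multiple hits
  t5 <- trial_record("T5", condition = "Gout and osteoarthritis; malaria")
  expect_setequal(baseline_classify(t5, names_idx),
                  c("malaria", "musculoskeletal"))
})

test_that("packaged category names drive the baseline on the 28 classes", {
  idx <- gbd28_names()
  expect_true(all(names(idx) %in% gbd28_grouping()$categories$id))
  t1 <- trial_record("T1", condition = "Acute hepatitis C infection")
  expect_equal(baseline_classify(t1, idx), "hepatitis")
})
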