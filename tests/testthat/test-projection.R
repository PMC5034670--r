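make_hierarchy_lexicon <- function() {
  concepts <- data.frame(
    cui = c("C100", "C200", "C300", "C400"),
    preferred_name = c("child asthma", "asthma", "respiratory disease",
                       "orphan condition"),
    semantic_types = "T047", stringsAsFactors = FALSE)
  terms <- data.frame(cui = concepts$cui,
                      term = concepts$preferred_name,
                      stringsAsFactors = FALSE)
  hierarchy <- data.frame(child_cui = c("C100", "C200", "C400"),
                          parent_cui = c("C200", "C300", "C300"),
                          stringsAsFactors = FALSE)
  crosswalk <- data.frame(cui = c("C200", "C300"),
                          icd10_spec = c("J45", "J00-J99.9"),
                          stringsAsFactors = FALSE)
  build_lexicon(concepts, terms, hierarchy, crosswalk)
}

test_that("restrict_to_icd10 returns direct crosswalk entries first", {
  lex <- fig1_lexicon()
  expect_equal(restrict_to_icd10("C0409959", lex), c("M16", "M16.9"))
  expect_error(restrict_to_icd10("C9999999", lex), "unknown cui")
})

test_that("restrict_to_icd10 ascends to the shallowest productive depth", {
  lex <- make_hierarchy_lexicon()
  # C100 has no entry; its parent C200 does -> stop there, never reach C300
  expect_equal(restrict_to_icd10("C100", lex), "J45")
  expect_equal(restrict_to_icd10("C200", lex), "J45")
  # no crosswalk anywhere above C0003864 (no hierarchy at all)
  expect_equal(restrict_to_icd10("C0003864", fig1_lexicon()), character(0))
})

test_that("adding a direct crosswalk entry only tightens the result", {
  lex <- make_hierarchy_lexicon()
  with_direct <- build_lexicon(
    lex$concepts[, 1:2] |> cbind(semantic_types = "T047"),
    lex$terms[, c("cui", "term")], lex$hierarchy,
    rbind(lex$crosswalk[, c("cui", "icd10_spec")],
          data.frame(cui = "C100", icd10_spec = "J45.0")))
  expect_equal(restrict_to_icd10("C100", with_direct), "J45.0")
})

test_that("concept_to_categories unions projections over all codes", {
  lex <- fig1_lexicon()
  g <- gbd28_grouping()
  cats <- concept_to_categories("C0409959", lex, g)
  expect_equal(unique(cats$category_id), "musculoskeletal")
  expect_false(any(cats$via_enrichment))
  expect_setequal(cats$icd10, c("M16", "M16.9"))
})

test_that("enrichment fires only when no automatic category exists", {
  g <- p37_grouping()
  concepts <- data.frame(cui = c("C1", "C2"),
                         preferred_name = c("perinatal infection",
                                            "congenital tuberculosis"),
                         semantic_types = "T047", stringsAsFactors = FALSE)
  terms <- data.frame(cui = c("C1", "C2"),
                      term = c("perinatal infection",
                               "congenital tuberculosis"),
                      stringsAsFactors = FALSE)
  crosswalk <- data.frame(cui = c("C1", "C2"),
                          icd10_spec = c("P37", "P37.0"),
                          stringsAsFactors = FALSE)
  lex <- build_lexicon(concepts, terms, crosswalk = crosswalk)
  enr <- build_enrichment(
    data.frame(cui = c("C1", "C2"),
               category_id = c("tuberculosis", "neonatal"),
               stringsAsFactors = FALSE), g)

  # C1's only code is the ambiguous P37: nothing automatic, enrichment used
  no_enr <- concept_to_categories("C1", lex, g)
  expect_equal(nrow(no_enr), 0L)
  with_enr <- concept_to_categories("C1", lex, g, enr)
  expect_equal(with_enr$category_id, "tuberculosis")
  expect_true(all(with_enr$via_enrichment))
  expect_true(all(is.na(with_enr$icd10)))

  # C2 projects automatically, so its enrichment entry must never fire
  auto <- concept_to_categories("C2", lex, g, enr)
  expect_equal(auto$category_id, "tuberculosis")
  expect_false(any(auto$via_enrichment))
})

test_that("build_pathways traces field-concept-code-category routes", {
  lex <- fig1_lexicon()
  g <- gbd28_grouping()
  trial <- fig1_trial()
  ann <- do.call(rbind, lapply(
    c("condition", "public_title", "scientific_title"),
    function(f) annotate(f, trial[[f]], lex)))
  paths <- build_pathways(trial$trial_id, ann, lex, g)
  expect_true(nrow(paths) > 0L)
  # the worked example: every pathway ends at musculoskeletal disorders
  expect_equal(unique(paths$category_id), "musculoskeletal")
  expect_setequal(unique(paths$field),
                  c("condition", "public_title", "scientific_title"))
  expect_false(any(duplicated(paths)))

  expect_equal(nrow(build_pathways("T1", NULL, lex, g)), 0L)
})

test_that("a block spanning two categories yields two pathways", {
  concepts <- data.frame(cui = "C10", preferred_name = "mixed condition",
                         semantic_types = "T047", stringsAsFactors = FALSE)
  terms <- data.frame(cui = "C10", term = "mixed condition",
                      stringsAsFactors = FALSE)
  crosswalk <- data.frame(cui = "C10", icd10_spec = "K10-K25.9",
                          stringsAsFactors = FALSE)
  lex <- build_lexicon(concepts, terms, crosswalk = crosswalk)
  g <- gbd28_grouping()
  ann <- annotate("condition", "mixed condition", lex)
  paths <- build_pathways("T1", ann, lex, g)
  expect_setequal(paths$category_id, c("oral", "digestive"))
  expect_equal(nrow(paths), 2L)
})

test_that("pathway traces serialize as JSON lines", {
  lex <- fig1_lexicon()
  g <- gbd28_grouping()
  ann <- annotate("condition", "Knee Osteoarthritis", lex)
  paths <- build_pathways("T1", ann, lex, g)
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  write_pathways(paths, tmp)
  lines <- readLines(tmp)
  expect_length(lines, nrow(paths))
  parsed <- jsonlite::fromJSON(lines[1])
  expect_equal(parsed$trial_id, "T1")
  expect_equal(parsed$category_id, "musculoskeletal")
})
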