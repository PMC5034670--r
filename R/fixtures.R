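#' @title Synthetic corpora for end-to-end testing
#' @description Generates self-consistent synthetic bundles — a disorder
#'   lexicon with synonyms and an ICD-10 crosswalk, a matching GBD-style
#'   grouping, and a trial corpus with gold labels — so that every stage of
#'   the pipeline is testable without any external download. Each synthetic
#'   category owns a disjoint ICD-10 letter range; gold labels are fixed at
#'   generation time and never re-derived, so classifier defects cannot
#'   silently redefine the truth. Controlled noise (empty condition fields,
#'   healthy-volunteer entries, ambiguous terms, typos, synonym swaps)
#'   emulates the data-quality problems of real registry records.
#' @name fixtures
NULL

.nato <- c("alpha", "bravo", "charlie", "delta", "echo", "foxtrot", "golf",
           "hotel", "india", "juliett", "kilo", "lima", "mike", "november",
           "oscar", "papa", "quebec", "romeo", "sierra", "tango", "uniform",
           "victor", "whiskey", "xray", "yankee", "zulu")

#' Specify a synthetic corpus
#'
#' @param n_trials Number of trial records.
#' @param n_categories Number of synthetic GBD-style categories (each owns
#'   one ICD-10 letter; at most 26).
#' @param terms_per_category Disorder concepts per category (at most 100,
#'   one ICD-10 major per concept).
#' @param p_empty_condition Probability that a trial's condition field is
#'   empty, the disease term appearing only in its titles.
#' @param p_title_only Probability that the condition field holds an
#'   uninformative entry while the disease term appears only in the titles.
#' @param p_healthy_volunteer Probability of a healthy-volunteer trial
#'   (gold label: no category).
#' @param p_ambiguous_term Probability that a trial's condition uses a term
#'   registered under two concepts in different categories (exercises
#'   disambiguation and the multiplicity rule).
#' @param p_multi_label Probability that a trial studies two categories.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_trials = 100, n_categories = 5,
                         terms_per_category = 4, p_empty_condition = 0,
                         p_title_only = 0, p_healthy_volunteer = 0,
                         p_ambiguous_term = 0, p_multi_label = 0, seed = 1) {
  probs <- c(p_empty_condition, p_title_only, p_healthy_volunteer,
             p_ambiguous_term, p_multi_label)
  stopifnot(n_trials >= 1, n_categories >= 1, terms_per_category >= 1,
            all(probs >= 0), all(probs <= 1))
  structure(list(n_trials = as.integer(n_trials),
                 n_categories = as.integer(n_categories),
                 terms_per_category = as.integer(terms_per_category),
                 p_empty_condition = p_empty_condition,
                 p_title_only = p_title_only,
                 p_healthy_volunteer = p_healthy_volunteer,
                 p_ambiguous_term = p_ambiguous_term,
                 p_multi_label = p_multi_label,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Run expr under a local RNG stream without disturbing the caller's.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic bundle
#'
#' Builds the lexicon, grouping, trial corpus and gold labels described by
#' a [fixture_spec()]. Category `i` owns the full range of ICD-10 letter
#' `i`; concept `j` of category `i` maps to the four-character code
#' `<letter><j>.0`, so every automatic pathway lands in its own category
#' and a clean corpus is classifiable with perfect accuracy. When `dir` is
#' given the bundle is also written to disk in the package's standard
#' formats (lexicon TSVs, `grouping.tsv`, `trials.csv` with ICTRP-style
#' headers, `gold.tsv`).
#'
#' @param spec A `fixture_spec`.
#' @param dir Optional output directory.
#' @return List with elements `lexicon`, `grouping`, `trials`, `gold`
#'   (data frame `trial_id`, `categories` semicolon-joined) and
#'   `ambiguous_terms`.
#' @export
generate_bundle <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_categories > length(.nato)) {
    stop(sprintf("cannot generate more than %d categories (one ICD-10 letter each)",
                 length(.nato)), call. = FALSE)
  }
  if (spec$terms_per_category > 100L) {
    stop("at most 100 concepts per category (one ICD-10 major each)",
         call. = FALSE)
  }
  .with_seed(spec$seed, .generate_bundle_impl(spec, dir))
}

.generate_bundle_impl <- function(spec, dir) {
  nc <- spec$n_categories
  tpc <- spec$terms_per_category
  letters_used <- LETTERS[seq_len(nc)]
  cat_ids <- paste0("cat_", .nato[seq_len(nc)])

  grouping <- build_grouping(
    category_id = cat_ids,
    category_name = paste("Synthetic category", toupper(.nato[seq_len(nc)])),
    residual = rep(FALSE, nc),
    icd10_spec = paste0(letters_used, "00-", letters_used, "99.9"),
    name = "synthetic")

  concepts <- list(); terms <- list(); crosswalk <- list()
  primary_term <- matrix("", nrow = nc, ncol = tpc)
  for (i in seq_len(nc)) {
    for (j in seq_len(tpc)) {
      cui <- sprintf("C%07d", i * 1000L + j)
      disease <- sprintf("%s disease %d", .nato[i], j)
      synonym <- sprintf("%s disorder %d", .nato[i], j)
      primary_term[i, j] <- disease
      concepts[[length(concepts) + 1L]] <- data.frame(
        cui = cui, preferred_name = disease, semantic_types = "T047",
        stringsAsFactors = FALSE)
      terms[[length(terms) + 1L]] <- data.frame(
        cui = cui, term = c(disease, synonym), stringsAsFactors = FALSE)
      crosswalk[[length(crosswalk) + 1L]] <- data.frame(
        cui = cui, icd10_spec = sprintf("%s%02d.0", letters_used[i], j - 1L),
        stringsAsFactors = FALSE)
    }
  }

  # ambiguous terms: one shared term per adjacent category pair, registered
  # under concept 1 of each category
  ambiguous <- character(0)
  if (spec$p_ambiguous_term > 0 && nc >= 2L) {
    for (i in seq_len(nc - 1L)) {
      shared <- sprintf("shared syndrome %d", i)
      ambiguous <- c(ambiguous, shared)
      terms[[length(terms) + 1L]] <- data.frame(
        cui = c(sprintf("C%07d", i * 1000L + 1L),
                sprintf("C%07d", (i + 1L) * 1000L + 1L)),
        term = shared, stringsAsFactors = FALSE)
    }
  }

  lexicon <- build_lexicon(do.call(rbind, concepts), do.call(rbind, terms),
                           crosswalk = do.call(rbind, crosswalk))

  # trials
  ids <- sprintf("SYN%05d", seq_len(spec$n_trials))
  condition <- character(spec$n_trials)
  public_title <- character(spec$n_trials)
  scientific_title <- character(spec$n_trials)
  gold <- character(spec$n_trials)
  for (t in seq_len(spec$n_trials)) {
    kind_draw <- stats::runif(4)
    ci <- sample.int(nc, 1L)
    cj <- sample.int(tpc, 1L)
    term <- primary_term[ci, cj]
    if (kind_draw[1] < spec$p_healthy_volunteer) {
      condition[t] <- "Healthy volunteers"
      public_title[t] <- "Study of healthy adult volunteers"
      scientific_title[t] <- "An open-label study in healthy volunteers"
      gold[t] <- ""
      next
    }
    if (kind_draw[2] < spec$p_ambiguous_term && length(ambiguous) > 0L) {
      k <- sample.int(length(ambiguous), 1L)
      condition[t] <- ambiguous[k]
      public_title[t] <- paste("Management of", ambiguous[k])
      scientific_title[t] <- paste("A trial of treatment for", ambiguous[k])
      gold[t] <- paste0("cat_", .nato[k])  # first of the two owning categories
      next
    }
    cats <- cat_ids[ci]
    terms_used <- term
    if (kind_draw[3] < spec$p_multi_label && nc >= 2L) {
      ci2 <- sample(setdiff(seq_len(nc), ci), 1L)
      cats <- c(cats, cat_ids[ci2])
      terms_used <- c(terms_used, primary_term[ci2, sample.int(tpc, 1L)])
    }
    text <- paste(terms_used, collapse = "; ")
    style_draw <- kind_draw[4]
    if (style_draw < spec$p_empty_condition) {
      condition[t] <- ""
    } else if (style_draw < spec$p_empty_condition + spec$p_title_only) {
      condition[t] <- "see study title"
    } else {
      condition[t] <- text
    }
    public_title[t] <- paste("Study of", text)
    scientific_title[t] <- paste(
      "A randomized controlled trial of treatment for", text)
    gold[t] <- paste(sort(cats), collapse = ";")
  }

  trials <- trial_record(ids, condition, public_title, scientific_title)
  gold_df <- data.frame(trial_id = ids, categories = gold,
                        stringsAsFactors = FALSE)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_lexicon(lexicon, file.path(dir, "lexicon"))
    write_grouping(grouping, file.path(dir, "grouping.tsv"))
    utils::write.csv(
      data.frame(TrialID = trials$trial_id,
                 Public_title = trials$public_title,
                 Scientific_title = trials$scientific_title,
                 Condition = trials$condition, stringsAsFactors = FALSE),
      file.path(dir, "trials.csv"), row.names = FALSE)
    write_gold(gold_df, file.path(dir, "gold.tsv"))
  }

  list(lexicon = lexicon, grouping = grouping, trials = trials,
       gold = gold_df, ambiguous_terms = ambiguous)
}

#' Apply controlled noise to trial texts
#'
#' Seeded, label-preserving perturbations: character-level typos (one
#' random letter substituted per affected word) and synonym swaps (a
#' lexicon term replaced by another synonym of the same concept). Gold
#' labels are untouched.
#'
#' @param trials A `trial_record` data frame.
#' @param typo_rate Per-word probability of a one-character typo.
#' @param synonym_swap_rate Per-field probability of swapping a recognized
#'   term for a synonym (requires `lexicon`).
#' @param seed Integer seed.
#' @param lexicon Lexicon supplying the synonym table (needed only when
#'   `synonym_swap_rate > 0`).
#' @return The perturbed `trial_record`.
#' @export
perturb <- function(trials, typo_rate = 0, synonym_swap_rate = 0, seed = 1,
                    lexicon = NULL) {
  stopifnot(typo_rate >= 0, typo_rate <= 1,
            synonym_swap_rate >= 0, synonym_swap_rate <= 1)
  if (synonym_swap_rate > 0 && is.null(lexicon)) {
    stop("synonym_swap_rate > 0 requires a lexicon", call. = FALSE)
  }
  if (typo_rate == 0 && synonym_swap_rate == 0) return(trials)
  .with_seed(seed, {
    for (field in .trial_fields) {
      for (t in seq_len(nrow(trials))) {
        text <- trials[[field]][t]
        if (!nzchar(text)) next
        if (synonym_swap_rate > 0 &&
            stats::runif(1) < synonym_swap_rate) {
          text <- .swap_synonym(text, lexicon)
        }
        if (typo_rate > 0) text <- .apply_typos(text, typo_rate)
        trials[[field]][t] <- text
      }
    }
    trials
  })
}

.apply_typos <- function(text, rate) {
  words <- strsplit(text, " ", fixed = TRUE)[[1]]
  for (w in seq_along(words)) {
    if (nchar(words[w]) > 0L && stats::runif(1) < rate) {
      pos <- sample.int(nchar(words[w]), 1L)
      substr(words[w], pos, pos) <- sample(letters, 1L)
    }
  }
  paste(words, collapse = " ")
}

.swap_synonym <- function(text, lexicon) {
  lowered <- tolower(text)
  for (i in seq_len(nrow(lexicon$terms))) {
    term <- tolower(lexicon$terms$term[i])
    idx <- regexpr(term, lowered, fixed = TRUE)
    if (idx > 0L) {
      others <- lexicon$terms$term[
        lexicon$terms$cui == lexicon$terms$cui[i] &
          tolower(lexicon$terms$term) != term]
      if (length(others) == 0L) next
      replacement <- sample(others, 1L)
      return(paste0(substring(text, 1L, idx - 1L), replacement,
                    substring(text, idx + nchar(term))))
    }
  }
  text
}
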