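#' @title Trial classification
#' @description The final stage: prioritization rules turn the set of
#'   pathways traced for a trial into its multi-label GBD classification
#'   (or "No GBD" when nothing survives). Three binary switches — word
#'   sense disambiguation, expert enrichment, and priority to the health
#'   condition field — give the 2 x 2 x 2 grid of eight classifier
#'   variants.
#' @name classifier
NULL

#' Construct trial records
#'
#' @param trial_id Registry identifier(s); must be non-empty.
#' @param condition,public_title,scientific_title Free-text fields
#'   (empty strings allowed; `NA` is mapped to `""`).
#' @return Data frame of class `trial_record` with one row per trial.
#' @export
trial_record <- function(trial_id, condition = "", public_title = "",
                         scientific_title = "") {
  n <- length(trial_id)
  fix <- function(x) {
    x <- rep_len(as.character(x), n)
    x[is.na(x)] <- ""
    x
  }
  trial_id <- as.character(trial_id)
  if (any(is.na(trial_id) | !nzchar(trial_id))) {
    stop("trial_id must be non-empty", call. = FALSE)
  }
  structure(
    data.frame(trial_id = trial_id, condition = fix(condition),
               public_title = fix(public_title),
               scientific_title = fix(scientific_title),
               stringsAsFactors = FALSE),
    class = c("trial_record", "data.frame")
  )
}

#' Configure a classifier variant
#'
#' @param wsd Use word-sense disambiguation (one concept per text span)?
#' @param enrichment Use the expert-enrichment table?
#' @param field_priority Give priority to the health-condition field?
#' @return A `classifier_config` list.
#' @seealso [classifier_variants()] for the full 8-variant grid.
#' @export
classifier_config <- function(wsd = TRUE, enrichment = TRUE,
                              field_priority = TRUE) {
  structure(list(wsd = isTRUE(wsd), enrichment = isTRUE(enrichment),
                 field_priority = isTRUE(field_priority)),
            class = "classifier_config")
}

#' The eight classifier variants
#'
#' Enumerates the 2 x 2 x 2 grid of [classifier_config()] settings.
#'
#' @return A list of 8 `classifier_config` objects, named
#'   `wsd<0|1>_enrich<0|1>_prio<0|1>`.
#' @export
classifier_variants <- function() {
  grid <- expand.grid(wsd = c(FALSE, TRUE), enrichment = c(FALSE, TRUE),
                      field_priority = c(FALSE, TRUE))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    classifier_config(grid$wsd[i], grid$enrichment[i], grid$field_priority[i])
  })
  names(out) <- sprintf("wsd%d_enrich%d_prio%d", as.integer(grid$wsd),
                        as.integer(grid$enrichment),
                        as.integer(grid$field_priority))
  out
}

#' Apply prioritization rules to a trial's pathways
#'
#' Two rules, in order. Field priority: when enabled and at least one
#' pathway issues from the health-condition field, only condition-field
#' pathways are retained (titles serve as a fallback when the condition
#' yields nothing). Multiplicity: each candidate category is scored by its
#' number of distinct (concept, ICD-10 spec) supports among the retained
#' pathways; when any category is supported at least twice, categories
#' supported only once are discarded as probable noise.
#'
#' @param pathways Data frame from [build_pathways()] for one trial.
#' @param config A `classifier_config`.
#' @return Character vector of category ids (possibly empty), sorted.
#' @export
prioritize <- function(pathways, config = classifier_config()) {
  if (is.null(pathways) || nrow(pathways) == 0L) return(character(0))
  retained <- pathways
  if (config$field_priority) {
    cond <- pathways[pathways$field == "condition", , drop = FALSE]
    if (nrow(cond) > 0L) retained <- cond
  }
  support <- unique(retained[, c("cui", "icd10", "category_id")])
  score <- table(support$category_id)
  if (max(score) >= 2L) score <- score[score >= 2L]
  sort(names(score))
}

#' Classify one trial record
#'
#' Runs the full pipeline: annotate the condition, public-title and
#' scientific-title fields (honoring `wsd`), derive pathways to candidate
#' categories (honoring `enrichment`), and apply the prioritization rules
#' (honoring `field_priority`). An empty final set yields a "No GBD"
#' classification.
#'
#' @param trial A one-row `trial_record` (or list with the same fields).
#' @param lexicon A `gbd_lexicon`.
#' @param grouping A `gbd_grouping`.
#' @param enrichment A `gbd_enrichment` or `NULL`.
#' @param config A `classifier_config`.
#' @param annotations Optional pre-computed annotations for this trial
#'   (data frame in the layout of [annotate()]); when supplied the built-in
#'   matcher is skipped.
#' @return A `gbd_classification`: list with `trial_id`, `categories`
#'   (sorted character vector, possibly empty), `no_gbd` flag and `trace`
#'   (the pathway data frame).
#' @export
classify_trial <- function(trial, lexicon, grouping, enrichment = NULL,
                           config = classifier_config(),
                           annotations = NULL) {
  if (length(trial$trial_id) != 1L || is.na(trial$trial_id) ||
      !nzchar(trial$trial_id)) {
    stop("trial record lacks a non-empty trial_id", call. = FALSE)
  }
  for (f in .trial_fields) {
    if (!is.character(trial[[f]]) || length(trial[[f]]) != 1L) {
      stop(sprintf("field '%s' is not a single character string", f),
           call. = FALSE)
    }
  }
  if (is.null(annotations)) {
    annotations <- do.call(rbind, lapply(.trial_fields, function(f) {
      annotate(f, trial[[f]], lexicon, wsd = config$wsd)
    }))
  }
  pathways <- build_pathways(
    trial$trial_id, annotations, lexicon, grouping,
    enrichment = if (config$enrichment) enrichment else NULL)
  categories <- prioritize(pathways, config)
  structure(
    list(trial_id = trial$trial_id, categories = categories,
         no_gbd = length(categories) == 0L, trace = pathways),
    class = "gbd_classification"
  )
}

#' @export
print.gbd_classification <- function(x, ...) {
  cat(sprintf("<classification %s> %s\n", x$trial_id,
              if (x$no_gbd) "No GBD" else paste(x$categories, collapse = "; ")))
  invisible(x)
}

#' Classify a batch of trial records
#'
#' Order-preserving map of [classify_trial()] over the rows of `trials`.
#' A failure on one record is logged (via `warning`) and recorded as a
#' skip; it never aborts the batch.
#'
#' @param trials A `trial_record` data frame.
#' @param lexicon,grouping,enrichment,config As in [classify_trial()].
#' @param annotations Optional named list `trial_id` -> annotation data
#'   frame (see [read_annotations()]).
#' @return A list of `gbd_classification` objects (skipped records carry
#'   `NULL`), with attribute `skipped`: data frame of `trial_id`, `reason`.
#' @export
classify_batch <- function(trials, lexicon, grouping, enrichment = NULL,
                           config = classifier_config(),
                           annotations = NULL) {
  skipped <- data.frame(trial_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    trial <- trials[i, , drop = FALSE]
    ann <- if (!is.null(annotations)) annotations[[trial$trial_id]] else NULL
    res <- tryCatch(
      classify_trial(trial, lexicon, grouping, enrichment, config,
                     annotations = ann),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("skipping trial %s: %s", trial$trial_id,
                      conditionMessage(res)), call. = FALSE)
      skipped <- rbind(skipped, data.frame(
        trial_id = trial$trial_id, reason = conditionMessage(res),
        stringsAsFactors = FALSE))
      out[i] <- list(NULL)
    } else {
      out[[i]] <- res
    }
  }
  attr(out, "skipped") <- skipped
  out
}

#' Verbatim disease-name baseline classifier
#'
#' A knowledge-free baseline: a trial is classified to a category when at
#' least one of the disease names defining that category appears verbatim
#' (case-insensitive, at word boundaries) in the selected text field(s).
#'
#' @param trial A one-row `trial_record`.
#' @param name_index Named list: category id -> character vector of
#'   defining disease names (see [gbd28_names()]).
#' @param fields Which fields to search: any subset of
#'   `c("condition", "public_title", "scientific_title")`.
#' @return Character vector of category ids (possibly empty), sorted.
#' @export
baseline_classify <- function(trial, name_index,
                              fields = .trial_fields) {
  fields <- match.arg(fields, .trial_fields, several.ok = TRUE)
  text <- paste(unlist(trial[fields]), collapse = " \n ")
  norm_text <- paste(normalize_text(text), collapse = " ")
  padded <- paste0(" ", norm_text, " ")
  hits <- character(0)
  for (cat in names(name_index)) {
    for (nm in name_index[[cat]]) {
      needle <- paste(normalize_text(nm), collapse = " ")
      if (nzchar(needle) &&
          grepl(paste0(" ", needle, " "), padded, fixed = TRUE)) {
        hits <- c(hits, cat)
        break
      }
    }
  }
  sort(unique(hits))
}
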