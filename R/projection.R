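#' @title Concept-to-category projection
#' @description The bridge between recognized concepts and GBD categories:
#'   each concept is projected to ICD-10 codes through the crosswalk (with a
#'   hierarchy-ascent fallback when the concept itself carries no mapping),
#'   the codes are projected onto categories under the unique-inclusion
#'   rule, and concepts left without any automatic category may be rescued
#'   by the expert-enrichment table. Every traced route from a trial field
#'   to a category is kept as a pathway for the prioritization rules and
#'   for audit.
#' @name concept_projection
NULL

#' Project a concept to ICD-10 codes
#'
#' Step 1 returns the concept's own crosswalk entries. Only when the concept
#' carries none does step 2 ascend the hierarchy breadth-first, stopping at
#' the first (shallowest) depth where any ancestor carries crosswalk
#' entries, and returning their union. No sibling or other lateral hops are
#' attempted.
#'
#' @param cui Concept id.
#' @param lexicon A `gbd_lexicon`.
#' @return Character vector of canonical ICD-10 code/block strings
#'   (possibly empty), sorted.
#' @export
restrict_to_icd10 <- function(cui, lexicon) {
  stopifnot(inherits(lexicon, "gbd_lexicon"))
  if (!(cui %in% lexicon$concepts$cui)) {
    stop(sprintf("unknown cui '%s'", cui), call. = FALSE)
  }
  direct <- lexicon$crosswalk$icd10_spec[lexicon$crosswalk$cui == cui]
  if (length(direct) > 0L) return(sort(unique(direct)))

  frontier <- cui
  seen <- cui
  repeat {
    parents <- unique(lexicon$hierarchy$parent_cui[
      lexicon$hierarchy$child_cui %in% frontier])
    parents <- setdiff(parents, seen)
    if (length(parents) == 0L) return(character(0))
    entries <- lexicon$crosswalk$icd10_spec[lexicon$crosswalk$cui %in% parents]
    if (length(entries) > 0L) return(sort(unique(entries)))
    seen <- c(seen, parents)
    frontier <- parents
  }
}

#' Project a concept to candidate GBD categories
#'
#' Unions [project_spec()] over the concept's ICD-10 codes. Only when that
#' union is empty, enrichment is enabled, and the concept appears in the
#' enrichment table are the table's categories returned, flagged as
#' enrichment-derived. Enrichment therefore never fires for a concept with
#' at least one automatic category.
#'
#' @param cui Concept id.
#' @param lexicon A `gbd_lexicon`.
#' @param grouping A `gbd_grouping`.
#' @param enrichment A `gbd_enrichment` or `NULL` (disabled).
#' @return Data frame with columns `category_id`, `via_enrichment`,
#'   `icd10` (the spec that produced the category; `NA` for enrichment
#'   rows). One row per (icd10, category) pair reached.
#' @export
concept_to_categories <- function(cui, lexicon, grouping, enrichment = NULL) {
  specs <- restrict_to_icd10(cui, lexicon)
  rows <- list()
  for (spec in specs) {
    cats <- project_spec(spec, grouping)
    for (cat in cats) {
      rows[[length(rows) + 1L]] <- data.frame(
        category_id = cat, via_enrichment = FALSE, icd10 = spec,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) > 0L) {
    out <- unique(do.call(rbind, rows))
    rownames(out) <- NULL
    return(out)
  }
  if (!is.null(enrichment) && !is.null(enrichment[[cui]])) {
    return(data.frame(category_id = enrichment[[cui]],
                      via_enrichment = TRUE, icd10 = NA_character_,
                      stringsAsFactors = FALSE))
  }
  data.frame(category_id = character(0), via_enrichment = logical(0),
             icd10 = character(0), stringsAsFactors = FALSE)
}

#' Build all pathways from a trial's annotations to GBD categories
#'
#' One pathway per distinct combination of field, concept, ICD-10 spec and
#' category reached; enrichment-derived pathways carry no ICD-10 spec.
#'
#' @param trial_id Trial identifier (carried through for audit).
#' @param annotations Data frame of annotations over the trial's fields
#'   (layout of [annotate()]).
#' @param lexicon A `gbd_lexicon`.
#' @param grouping A `gbd_grouping`.
#' @param enrichment A `gbd_enrichment` or `NULL`.
#' @return Data frame with columns `trial_id`, `field`, `cui`, `icd10`,
#'   `category_id`, `via_enrichment`.
#' @export
build_pathways <- function(trial_id, annotations, lexicon, grouping,
                           enrichment = NULL) {
  empty <- data.frame(trial_id = character(0), field = character(0),
                      cui = character(0), icd10 = character(0),
                      category_id = character(0),
                      via_enrichment = logical(0), stringsAsFactors = FALSE)
  if (is.null(annotations) || nrow(annotations) == 0L) return(empty)
  pairs <- unique(annotations[, c("field", "cui")])
  cuis <- unique(pairs$cui)
  cat_cache <- lapply(cuis, concept_to_categories, lexicon = lexicon,
                      grouping = grouping, enrichment = enrichment)
  names(cat_cache) <- cuis
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    cats <- cat_cache[[pairs$cui[i]]]
    if (nrow(cats) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      trial_id = trial_id, field = pairs$field[i], cui = pairs$cui[i],
      icd10 = cats$icd10, category_id = cats$category_id,
      via_enrichment = cats$via_enrichment, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Write pathways as JSON lines for audit
#'
#' @param pathways Data frame from [build_pathways()].
#' @param path Output file; one JSON object per pathway per line.
#' @return `path`, invisibly.
#' @export
write_pathways <- function(pathways, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(pathways))) {
    writeLines(jsonlite::toJSON(as.list(pathways[i, , drop = FALSE]),
                                auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}
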