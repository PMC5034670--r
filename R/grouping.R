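#' @title GBD groupings
#' @description A GBD grouping partitions ICD-10 space into named categories
#'   of the Global Burden of Diseases cause list. Each category is defined by
#'   a set of ICD-10 codes and blocks; residual catch-all categories may be
#'   carried for bookkeeping but are never assignable by the classifier.
#' @name gbd_grouping
NULL

#' Load a GBD grouping from a TSV file
#'
#' The file must be UTF-8 TSV with a header row and columns `category_id`,
#' `category_name`, `residual_flag` (0/1) and `icd10_spec` (one code or
#' block per row; may be empty for categories carried without assignments).
#' All specs are parsed and expanded into a code map; validation collects
#' duplicate category ids, unparsable specs, and four-character codes
#' claimed by two distinct non-residual categories.
#'
#' @param path Path to the grouping TSV.
#' @param name Grouping name; defaults to the file name.
#' @return An object of class `gbd_grouping` with elements `name`,
#'   `categories` (data frame: `id`, `name`, `residual`), `assignments`
#'   (named list of spec strings per category) and `code_map` (data frame:
#'   `code`, `category_id` over expanded four- and three-character codes).
#' @seealso [gbd28_grouping()] for the packaged 28-class grouping.
#' @export
load_grouping <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("grouping file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8")
  required <- c("category_id", "category_name", "residual_flag", "icd10_spec")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("grouping file missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("grouping file contains no categories", call. = FALSE)
  }
  build_grouping(
    category_id = df$category_id,
    category_name = df$category_name,
    residual = df$residual_flag %in% c("1", "TRUE", "true"),
    icd10_spec = df$icd10_spec,
    name = if (is.null(name)) basename(path) else name
  )
}

#' Construct a GBD grouping from vectors of rows
#'
#' Programmatic counterpart of [load_grouping()]: each element describes one
#' row of the grouping table (a category may span several rows, one ICD-10
#' spec each).
#'
#' @param category_id,category_name,residual,icd10_spec Parallel vectors.
#' @param name Grouping name.
#' @return A `gbd_grouping`; see [load_grouping()].
#' @export
build_grouping <- function(category_id, category_name, residual, icd10_spec,
                           name = "grouping") {
  stopifnot(length(category_id) == length(category_name),
            length(category_id) == length(residual),
            length(category_id) == length(icd10_spec))
  rows <- data.frame(category_id = as.character(category_id),
                     category_name = as.character(category_name),
                     residual = as.logical(residual),
                     icd10_spec = trimws(as.character(icd10_spec)),
                     stringsAsFactors = FALSE)

  first <- !duplicated(rows$category_id)
  categories <- data.frame(id = rows$category_id[first],
                           name = rows$category_name[first],
                           residual = rows$residual[first],
                           stringsAsFactors = FALSE)
  # a category id must not reappear with a different name or residual flag
  for (i in which(!first)) {
    j <- match(rows$category_id[i], categories$id)
    if (!identical(rows$category_name[i], categories$name[j]) ||
        !identical(rows$residual[i], categories$residual[j])) {
      stop(sprintf("category '%s' redefined with conflicting name/flag",
                   rows$category_id[i]), call. = FALSE)
    }
  }

  errors <- character(0)
  assignments <- list()
  map_code <- character(0)
  map_cat <- character(0)
  for (i in seq_len(nrow(rows))) {
    spec <- rows$icd10_spec[i]
    if (!nzchar(spec)) next
    parsed <- tryCatch(parse_icd10(spec), error = function(e) e)
    if (inherits(parsed, "error")) {
      errors <- c(errors, sprintf("row %d: %s", i, conditionMessage(parsed)))
      next
    }
    canon <- format(parsed)
    assignments[[rows$category_id[i]]] <-
      c(assignments[[rows$category_id[i]]], canon)
    codes <- expand_block(parsed)
    map_code <- c(map_code, codes)
    map_cat <- c(map_cat, rep(rows$category_id[i], length(codes)))
  }

  code_map <- data.frame(code = map_code, category_id = map_cat,
                         stringsAsFactors = FALSE)
  code_map <- unique(code_map)

  # mutual exclusivity: no four-character code claimed by two non-residual
  # categories (three-character rows are summaries of their extensions and
  # are checked at the same granularity)
  nr_ids <- categories$id[!categories$residual]
  nr_map <- code_map[code_map$category_id %in% nr_ids, , drop = FALSE]
  dup <- nr_map$code[duplicated(nr_map$code)]
  if (length(dup) > 0L) {
    collisions <- unique(dup)
    for (code in utils::head(collisions, 20L)) {
      cats <- nr_map$category_id[nr_map$code == code]
      errors <- c(errors, sprintf(
        "code %s claimed by non-residual categories: %s",
        code, paste(unique(cats), collapse = ", ")))
    }
  }

  if (length(errors) > 0L) {
    stop(paste0("invalid grouping:\n  ",
                paste(errors, collapse = "\n  ")), call. = FALSE)
  }

  # hashed lookup: canonical code -> non-residual category id
  nr_env <- new.env(parent = emptyenv(), size = max(29L, nrow(nr_map)))
  for (i in seq_len(nrow(nr_map))) {
    assign(nr_map$code[i], nr_map$category_id[i], envir = nr_env)
  }
  structure(
    list(name = name, categories = categories, assignments = assignments,
         code_map = code_map,
         .nonresidual_map = nr_env,
         .nonresidual_codes = nr_map$code,
         # codes a block projection needs to visit: mapped codes plus the
         # three-character parents of mapped codes
         .projection_universe = unique(c(nr_map$code,
                                         .icd10_parent(nr_map$code)))),
    class = "gbd_grouping"
  )
}

#' @export
print.gbd_grouping <- function(x, ...) {
  cat(sprintf("<GBD grouping '%s'>\n", x$name))
  cat(sprintf("  %d categories (%d non-residual, %d residual)\n",
              nrow(x$categories), sum(!x$categories$residual),
              sum(x$categories$residual)))
  cat(sprintf("  %d mapped ICD-10 codes\n", nrow(x$code_map)))
  invisible(x)
}

#' Write a grouping back to its TSV form
#'
#' @param grouping A `gbd_grouping`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grouping <- function(grouping, path) {
  stopifnot(inherits(grouping, "gbd_grouping"))
  rows <- do.call(rbind, lapply(grouping$categories$id, function(id) {
    specs <- grouping$assignments[[id]]
    if (is.null(specs)) specs <- ""
    j <- match(id, grouping$categories$id)
    data.frame(category_id = id,
               category_name = grouping$categories$name[j],
               residual_flag = as.integer(grouping$categories$residual[j]),
               icd10_spec = specs, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged 28-class GBD grouping
#'
#' Loads the grouping of the GBD 2010 cause list into 28 assignable
#' categories plus 2 residual categories ("Other infectious diseases";
#' "Other endocrine, nutritional, blood, and immune disorders") that are
#' carried for bookkeeping but excluded from classification. The ICD-10
#' assignments shipped with the package are a curation written for this
#' artifact: they follow the named constituent causes of each category, not
#' any licensed code list, and are documented as such.
#'
#' @return A `gbd_grouping` with 30 categories, 28 of them non-residual.
#' @export
gbd28_grouping <- function() {
  path <- system.file("extdata", "gbd28.tsv", package = "gbdtrials",
                      mustWork = TRUE)
  load_grouping(path, name = "gbd28")
}

#' Packaged disease names defining each 28-class category
#'
#' Returns the constituent cause names of each category of the 28-class
#' grouping (e.g. "Asthma" for Chronic respiratory diseases), as used by the
#' verbatim-match baseline classifier.
#'
#' @return Named list mapping category id to a character vector of names.
#' @seealso [baseline_classify()]
#' @export
gbd28_names <- function() {
  path <- system.file("extdata", "gbd28_names.tsv", package = "gbdtrials",
                      mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  split(df$name, df$category_id)
}

#' Project one ICD-10 code onto a GBD category
#'
#' A code is projected only when it is totally included in a unique
#' non-residual category. A four-character code takes its own mapped
#' category, falling back to its three-character parent's category when only
#' the parent is mapped. A three-character code is projected only when the
#' code itself and every one of its mapped four-character extensions fall in
#' a single category; if its extensions split across two or more categories
#' (e.g. a perinatal infection code whose `.0` is tuberculosis and `.3` a
#' parasitic disease) the code is ambiguous and projects to nothing.
#' Residual categories are never returned.
#'
#' @param code An `icd10_code` or canonical code string.
#' @param grouping A validated `gbd_grouping`.
#' @return A category id string, or `NA_character_` when no unambiguous
#'   non-residual category exists.
#' @export
project_code <- function(code, grouping) {
  stopifnot(inherits(grouping, "gbd_grouping"))
  code_str <- .icd10_canonical(code)
  map <- grouping$.nonresidual_map
  if (.icd10_has_minor(code_str)) {
    hit <- get0(code_str, envir = map, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    parent <- .icd10_parent(code_str)
    hit <- get0(parent, envir = map, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    return(NA_character_)
  }
  # three-character code: itself plus all mapped extensions must agree
  members <- c(code_str, paste0(code_str, ".", 0:9))
  cats <- unique(unlist(lapply(members, get0, envir = map,
                               inherits = FALSE)))
  if (length(cats) == 1L) cats else NA_character_
}

#' Project an ICD-10 code or block onto candidate GBD categories
#'
#' For a single code this is the zero- or one-element set from
#' [project_code()]. A block is split into its constituent three- and
#' four-character codes and projected code by code; the result is the union
#' of the individual projections. Block expansion is restricted to codes
#' known to the grouping (mapped codes and the three-character parents of
#' mapped codes), so unmapped stretches of a wide block contribute nothing.
#'
#' @param spec An `icd10_code`, `icd10_block`, or parseable string.
#' @param grouping A validated `gbd_grouping`.
#' @return Character vector of category ids (possibly empty), sorted.
#' @export
project_spec <- function(spec, grouping) {
  stopifnot(inherits(grouping, "gbd_grouping"))
  if (is.character(spec)) spec <- parse_icd10(spec)
  if (inherits(spec, "icd10_code")) {
    hit <- project_code(spec, grouping)
    return(if (is.na(hit)) character(0) else hit)
  }
  codes <- expand_block(spec, universe = grouping$.projection_universe)
  hits <- vapply(codes, project_code, character(1), grouping = grouping)
  sort(unique(hits[!is.na(hits)]))
}
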