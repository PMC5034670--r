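#' @title Mini-metathesaurus lexicon
#' @description An open TSV bundle standing in for a licensed
#'   metathesaurus subset: concepts with semantic types, synonym terms,
#'   a concept hierarchy, a concept-to-ICD-10 crosswalk, and an optional
#'   expert-enrichment table. Any real metathesaurus subset can be
#'   exported into this layout.
#' @name lexicon
NULL

#' Default disorder semantic-type codes
#'
#' Semantic types counted as diseases or injuries when filtering recognized
#' concepts. The default follows the conventional "disorders" semantic
#' group of biomedical metathesauri (disease or syndrome, neoplastic
#' process, mental dysfunction, injury, congenital/acquired abnormality,
#' pathologic function, sign or symptom).
#'
#' @return Character vector of semantic-type codes.
#' @export
default_disorder_types <- function() {
  c("T019", "T020", "T037", "T046", "T047", "T048", "T049",
    "T050", "T184", "T190", "T191")
}

#' Load a lexicon bundle from a directory
#'
#' Expects UTF-8 TSV files with header rows: `concepts.tsv`
#' (`cui`, `preferred_name`, `semantic_types` semicolon-joined),
#' `terms.tsv` (`cui`, `term`), `hierarchy.tsv` (`child_cui`,
#' `parent_cui`) and `crosswalk.tsv` (`cui`, `icd10_spec`). Hierarchy and
#' crosswalk may be empty (header only). All cui references are validated
#' against the concept table, the hierarchy is checked for cycles, and
#' terms are normalized with the same rules used by the annotator.
#'
#' @param dir Directory containing the four TSV files.
#' @param disorder_types Semantic types counted as disorders; defaults to
#'   [default_disorder_types()].
#' @return An object of class `gbd_lexicon`.
#' @export
load_lexicon <- function(dir, disorder_types = default_disorder_types()) {
  read_tsv <- function(file, cols) {
    path <- file.path(dir, file)
    if (!file.exists(path)) {
      stop(sprintf("lexicon bundle missing %s", file), call. = FALSE)
    }
    df <- utils::read.delim(path, sep = "\t", quote = "",
                            stringsAsFactors = FALSE,
                            colClasses = "character",
                            fileEncoding = "UTF-8")
    missing <- setdiff(cols, names(df))
    if (length(missing) > 0L) {
      stop(sprintf("%s missing column(s): %s", file,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    df
  }
  concepts <- read_tsv("concepts.tsv",
                       c("cui", "preferred_name", "semantic_types"))
  terms <- read_tsv("terms.tsv", c("cui", "term"))
  hierarchy <- read_tsv("hierarchy.tsv", c("child_cui", "parent_cui"))
  crosswalk <- read_tsv("crosswalk.tsv", c("cui", "icd10_spec"))
  build_lexicon(concepts, terms, hierarchy, crosswalk, disorder_types)
}

#' Construct a lexicon from in-memory tables
#'
#' Programmatic counterpart of [load_lexicon()]; see that function for the
#' table layouts and validation rules.
#'
#' @param concepts,terms,hierarchy,crosswalk Data frames.
#' @param disorder_types Semantic types counted as disorders.
#' @return A `gbd_lexicon`.
#' @export
build_lexicon <- function(concepts, terms,
                          hierarchy = data.frame(child_cui = character(0),
                                                 parent_cui = character(0)),
                          crosswalk = data.frame(cui = character(0),
                                                 icd10_spec = character(0)),
                          disorder_types = default_disorder_types()) {
  errors <- character(0)

  dup <- concepts$cui[duplicated(concepts$cui)]
  if (length(dup) > 0L) {
    errors <- c(errors, sprintf("duplicate cui in concepts: %s",
                                paste(unique(dup), collapse = ", ")))
  }
  bad_cui <- concepts$cui[!grepl("^C[0-9]+$", concepts$cui)]
  if (length(bad_cui) > 0L) {
    errors <- c(errors, sprintf("malformed cui: %s",
                                paste(utils::head(bad_cui, 5), collapse = ", ")))
  }
  stypes <- strsplit(concepts$semantic_types, ";", fixed = TRUE)
  stypes <- lapply(stypes, function(x) trimws(x[nzchar(trimws(x))]))
  if (any(lengths(stypes) == 0L)) {
    rows <- which(lengths(stypes) == 0L)
    errors <- c(errors, sprintf("concept row(s) without semantic type: %s",
                                paste(utils::head(rows, 5), collapse = ", ")))
  }

  check_ref <- function(cuis, what) {
    dangling <- which(!(cuis %in% concepts$cui))
    if (length(dangling) > 0L) {
      errors <<- c(errors, sprintf(
        "%s row(s) %s reference unknown cui(s): %s", what,
        paste(utils::head(dangling, 5), collapse = ", "),
        paste(utils::head(unique(cuis[dangling]), 5), collapse = ", ")))
    }
  }
  check_ref(terms$cui, "terms")
  if (nrow(hierarchy) > 0L) {
    check_ref(hierarchy$child_cui, "hierarchy (child)")
    check_ref(hierarchy$parent_cui, "hierarchy (parent)")
    if (.has_cycle(hierarchy$child_cui, hierarchy$parent_cui)) {
      errors <- c(errors, "hierarchy contains a cycle")
    }
  }
  if (nrow(crosswalk) > 0L) {
    check_ref(crosswalk$cui, "crosswalk")
    for (i in seq_len(nrow(crosswalk))) {
      parsed <- tryCatch(parse_icd10(crosswalk$icd10_spec[i]),
                         error = function(e) e)
      if (inherits(parsed, "error")) {
        errors <- c(errors, sprintf("crosswalk row %d: %s", i,
                                    conditionMessage(parsed)))
      } else {
        crosswalk$icd10_spec[i] <- format(parsed)
      }
    }
  }

  if (length(errors) > 0L) {
    stop(paste0("invalid lexicon:\n  ", paste(errors, collapse = "\n  ")),
         call. = FALSE)
  }

  concepts_df <- data.frame(cui = concepts$cui,
                            preferred_name = concepts$preferred_name,
                            stringsAsFactors = FALSE)
  concepts_df$semantic_types <- stypes

  # normalized term -> character vector of cuis (hash for O(1) lookup)
  terms$term_norm <- vapply(terms$term,
                            function(t) paste(normalize_text(t), collapse = " "),
                            character(1), USE.NAMES = FALSE)
  terms <- terms[nzchar(terms$term_norm), , drop = FALSE]
  term_index <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(terms))) {
    key <- terms$term_norm[i]
    term_index[[key]] <- unique(c(term_index[[key]], terms$cui[i]))
  }
  max_term_tokens <- if (nrow(terms) > 0L) {
    max(lengths(strsplit(terms$term_norm, " ", fixed = TRUE)))
  } else 0L

  # cui -> disorder flag
  is_disorder <- vapply(stypes, function(s) any(s %in% disorder_types),
                        logical(1))

  structure(
    list(concepts = concepts_df,
         terms = terms[, c("cui", "term", "term_norm")],
         hierarchy = hierarchy,
         crosswalk = crosswalk,
         disorder_types = disorder_types,
         .term_index = term_index,
         .max_term_tokens = max_term_tokens,
         .disorder = stats::setNames(is_disorder, concepts$cui),
         .preferred = stats::setNames(concepts$preferred_name, concepts$cui)),
    class = "gbd_lexicon"
  )
}

# Kahn-style cycle detection on the child -> parent edge list.
.has_cycle <- function(child, parent) {
  nodes <- unique(c(child, parent))
  edges <- data.frame(from = child, to = parent, stringsAsFactors = FALSE)
  repeat {
    if (nrow(edges) == 0L) return(FALSE)
    sinks <- setdiff(nodes, edges$from)
    keep <- !(edges$to %in% sinks)
    if (all(keep)) return(TRUE)  # no removable edge left -> cycle
    edges <- edges[keep, , drop = FALSE]
    nodes <- unique(c(edges$from, edges$to))
  }
}

#' @export
print.gbd_lexicon <- function(x, ...) {
  cat("<lexicon>\n")
  cat(sprintf("  %d concepts (%d disorder), %d terms, %d hierarchy edges, %d crosswalk rows\n",
              nrow(x$concepts), sum(x$.disorder), nrow(x$terms),
              nrow(x$hierarchy), nrow(x$crosswalk)))
  invisible(x)
}

#' Write a lexicon bundle to a directory
#'
#' Emits the four TSV files read by [load_lexicon()].
#'
#' @param lexicon A `gbd_lexicon`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_lexicon <- function(lexicon, dir) {
  stopifnot(inherits(lexicon, "gbd_lexicon"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  concepts <- data.frame(
    cui = lexicon$concepts$cui,
    preferred_name = lexicon$concepts$preferred_name,
    semantic_types = vapply(lexicon$concepts$semantic_types,
                            paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  w(concepts, "concepts.tsv")
  w(lexicon$terms[, c("cui", "term")], "terms.tsv")
  w(lexicon$hierarchy, "hierarchy.tsv")
  w(lexicon$crosswalk, "crosswalk.tsv")
  invisible(dir)
}

#' Load an expert-enrichment table
#'
#' The enrichment table routes concepts that have no automatic pathway to
#' hand-assigned GBD categories. TSV with columns `cui`, `category_id`;
#' every category id must exist in the active grouping.
#'
#' @param path TSV file path.
#' @param grouping The active `gbd_grouping`.
#' @return An object of class `gbd_enrichment`: named list mapping cui to a
#'   character vector of category ids.
#' @export
load_enrichment <- function(path, grouping) {
  stopifnot(inherits(grouping, "gbd_grouping"))
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8")
  missing <- setdiff(c("cui", "category_id"), names(df))
  if (length(missing) > 0L) {
    stop(sprintf("enrichment file missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  build_enrichment(df, grouping)
}

#' Construct an enrichment table from a data frame
#'
#' @param df Data frame with columns `cui`, `category_id`.
#' @param grouping The active `gbd_grouping`.
#' @return A `gbd_enrichment`.
#' @export
build_enrichment <- function(df, grouping) {
  bad <- setdiff(unique(df$category_id), grouping$categories$id)
  if (length(bad) > 0L) {
    stop(sprintf("enrichment references unknown category id(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  entries <- if (nrow(df) > 0L) {
    lapply(split(df$category_id, df$cui), unique)
  } else {
    stats::setNames(list(), character(0))
  }
  structure(entries, class = "gbd_enrichment")
}
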