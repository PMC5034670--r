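#' @title Registry input and result output
#' @description Readers for trial records in WHO ICTRP export form (XML or
#'   CSV) and ClinicalTrials.gov study XML, and writers/readers for the
#'   package's classification, gold-label and evaluation-report formats.
#'   Nothing is dropped silently: every skipped record is reported with a
#'   reason.
#' @name io_registry
NULL

# Configurable field-name mapping: export dialects drift, so the mapping
# from source element/column names to trial_record fields is data.
.ictrp_field_map <- c(trial_id = "TrialID", public_title = "Public_title",
                      scientific_title = "Scientific_title",
                      condition = "Condition")

#' Read trial records from a WHO ICTRP export
#'
#' Accepts the XML dialect (`Trial` elements with `TrialID`,
#' `Public_title`, `Scientific_title`, `Condition` children) or a CSV with
#' the equivalent headers. Missing text fields become empty strings; a
#' missing trial id is an error. Multi-entry condition fields (semicolon or
#' line-break separated) are kept as a single string — the separator is
#' preserved and handled downstream by text normalization.
#'
#' @param path Input file.
#' @param format `"auto"` (by file extension), `"xml"` or `"csv"`.
#' @param field_map Named character vector mapping `trial_record` fields to
#'   source names; override to absorb export-format drift.
#' @return A `trial_record` data frame.
#' @export
read_ictrp <- function(path, format = c("auto", "xml", "csv"),
                       field_map = .ictrp_field_map) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "xml"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
    if (!(field_map[["trial_id"]] %in% names(df))) {
      stop(sprintf("%s: missing column '%s'", path, field_map[["trial_id"]]),
           call. = FALSE)
    }
    get <- function(col) {
      if (col %in% names(df)) df[[col]] else rep("", nrow(df))
    }
    ids <- df[[field_map[["trial_id"]]]]
    if (any(!nzchar(ids))) {
      stop(sprintf("%s: empty trial id at row(s) %s", path,
                   paste(utils::head(which(!nzchar(ids)), 5), collapse = ", ")),
           call. = FALSE)
    }
    return(trial_record(ids,
                        condition = get(field_map[["condition"]]),
                        public_title = get(field_map[["public_title"]]),
                        scientific_title = get(field_map[["scientific_title"]])))
  }
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//Trial")
  if (length(nodes) == 0L) {
    stop(sprintf("%s: no Trial elements found", path), call. = FALSE)
  }
  field_of <- function(node, name) {
    child <- xml2::xml_find_first(node, name)
    if (inherits(child, "xml_missing")) "" else trimws(xml2::xml_text(child))
  }
  rows <- lapply(seq_along(nodes), function(i) {
    node <- nodes[[i]]
    id <- field_of(node, field_map[["trial_id"]])
    if (!nzchar(id)) {
      stop(sprintf("%s: Trial element %d lacks %s", path, i,
                   field_map[["trial_id"]]), call. = FALSE)
    }
    data.frame(trial_id = id,
               condition = field_of(node, field_map[["condition"]]),
               public_title = field_of(node, field_map[["public_title"]]),
               scientific_title = field_of(node, field_map[["scientific_title"]]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  trial_record(df$trial_id, df$condition, df$public_title,
               df$scientific_title)
}

#' Read trial records from ClinicalTrials.gov study XML
#'
#' Maps `brief_title` to the public title, `official_title` to the
#' scientific title and joins multiple `condition` elements into one
#' condition string (semicolon separated). The trial id is taken from
#' `id_info/nct_id`. The file may hold a single `clinical_study` root or a
#' collection of such elements.
#'
#' @param path Study XML file.
#' @return A `trial_record` data frame.
#' @export
read_ctgov <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//clinical_study")
  if (length(nodes) == 0L && xml2::xml_name(doc) == "clinical_study") {
    nodes <- list(doc)
  }
  if (length(nodes) == 0L) {
    stop(sprintf("%s: no clinical_study elements found", path), call. = FALSE)
  }
  text_of <- function(node, xpath) {
    child <- xml2::xml_find_first(node, xpath)
    if (inherits(child, "xml_missing")) "" else trimws(xml2::xml_text(child))
  }
  rows <- lapply(seq_along(nodes), function(i) {
    node <- nodes[[i]]
    id <- text_of(node, ".//id_info/nct_id")
    if (!nzchar(id)) {
      stop(sprintf("%s: clinical_study element %d lacks id_info/nct_id",
                   path, i), call. = FALSE)
    }
    conditions <- trimws(xml2::xml_text(
      xml2::xml_find_all(node, "./condition")))
    data.frame(trial_id = id,
               condition = paste(conditions[nzchar(conditions)],
                                 collapse = "; "),
               public_title = text_of(node, "./brief_title"),
               scientific_title = text_of(node, "./official_title"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  trial_record(df$trial_id, df$condition, df$public_title,
               df$scientific_title)
}

#' Write classifications to TSV
#'
#' Columns `trial_id`, `categories` (semicolon-joined ids, empty when
#' none) and `no_gbd` (0/1), in stable order.
#'
#' @param results List of `gbd_classification`s (or a data frame already in
#'   the output layout).
#' @param path Output TSV path.
#' @param trace Optional path for a JSON-lines pathway trace.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(results, path, trace = NULL) {
  if (is.data.frame(results)) {
    df <- results
  } else {
    results <- Filter(Negate(is.null), results)
    df <- data.frame(
      trial_id = vapply(results, function(x) x$trial_id, character(1)),
      categories = vapply(results, function(x) {
        paste(x$categories, collapse = ";")
      }, character(1)),
      no_gbd = vapply(results, function(x) as.integer(x$no_gbd), integer(1)),
      stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(trace) && !is.data.frame(results)) {
    traces <- do.call(rbind, lapply(results, function(x) x$trace))
    write_pathways(traces, trace)
  }
  invisible(path)
}

#' Read a classification TSV
#'
#' @param path File written by [write_classifications()].
#' @return Data frame `trial_id`, `categories`, `no_gbd`.
#' @export
read_classifications <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = c(trial_id = "character",
                                         categories = "character"),
                          fileEncoding = "UTF-8")
  df$categories[is.na(df$categories)] <- ""
  df
}

#' Write / read gold-standard labels
#'
#' TSV with columns `trial_id`, `categories` (semicolon-joined, empty for
#' "No GBD").
#'
#' @param gold Data frame `trial_id`, `categories`.
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_gold <- function(gold, path) {
  utils::write.table(gold[, c("trial_id", "categories")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_gold
#' @export
read_gold <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  df$categories[is.na(df$categories)] <- ""
  df
}

#' Write an evaluation report
#'
#' Emits a per-category TSV (one row per category plus "No GBD", columns
#' mirroring the diagnostic-accuracy table: counts, Sen/Spe/PPV with CI
#' bounds, LR+/LR-) and a JSON file with the full report including the
#' exact-matching strata and weighted averages. Undefined metrics are
#' written as "-" in the TSV and `null` in the JSON.
#'
#' @param report A `gbd_eval_report` from [evaluate_classifications()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "gbd_eval_report"))
  tsv_path <- paste0(prefix, ".tsv")
  json_path <- paste0(prefix, ".json")
  pc <- report$per_category
  fmt <- function(x, digits = 3) ifelse(is.na(x), "-", round(x, digits))
  out <- data.frame(category_id = pc$category_id, tp = pc$tp, fp = pc$fp,
                    tn = pc$tn, fn = pc$fn,
                    sensitivity = fmt(pc$sensitivity),
                    sensitivity_ci = paste0("[", fmt(pc$sensitivity_lo), "-",
                                            fmt(pc$sensitivity_hi), "]"),
                    specificity = fmt(pc$specificity),
                    specificity_ci = paste0("[", fmt(pc$specificity_lo), "-",
                                            fmt(pc$specificity_hi), "]"),
                    ppv = fmt(pc$ppv),
                    lr_plus = fmt(pc$lr_plus, 2),
                    lr_minus = fmt(pc$lr_minus, 3),
                    stringsAsFactors = FALSE)
  utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, na = "null", dataframe = "rows")
  invisible(c(tsv_path, json_path))
}
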