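#' @title Concept recognition in trial text
#' @description A deterministic exact dictionary matcher recognizes disorder
#'   concepts in the free-text fields of a trial record: the text is
#'   normalized, scanned greedily for the leftmost-longest spans matching a
#'   lexicon term, and each matching span is annotated with every disorder
#'   concept carrying that term. An optional disambiguation step keeps a
#'   single concept per span. Externally produced annotations (e.g. from a
#'   full-scale concept recognizer) can be ingested instead via
#'   [read_annotations()].
#' @name annotation
NULL

.trial_fields <- c("condition", "public_title", "scientific_title")

#' Normalize free text into tokens
#'
#' Lowercases, maps punctuation to spaces and splits on whitespace.
#' Deterministic; the same normalization is applied to lexicon terms, so a
#' term matches irrespective of case and punctuation style.
#'
#' @param text A character string (possibly empty or `NA`).
#' @return Character vector of tokens (length zero for empty input).
#' @examples
#' normalize_text("HIV/AIDS")   # "hiv"  "aids"
#' @export
normalize_text <- function(text) {
  if (length(text) != 1L || is.na(text)) return(character(0))
  mapped <- gsub("[^a-z0-9]", " ", tolower(text))
  tokens <- strsplit(trimws(mapped), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

# Tokenize preserving character offsets in the original string.
# Returns data.frame(token, start, end) with 1-based inclusive offsets.
.tokenize_with_spans <- function(text) {
  mapped <- gsub("[^a-z0-9]", " ", tolower(text))
  m <- gregexpr("[a-z0-9]+", mapped)[[1]]
  if (m[1L] == -1L) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0)))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(token = substring(mapped, starts, starts + lens - 1L),
             start = starts, end = starts + lens - 1L,
             stringsAsFactors = FALSE)
}

#' Annotate one text field with disorder concepts
#'
#' Scans the normalized token sequence greedily left to right, at each
#' position taking the longest token n-gram that equals a lexicon term with
#' at least one disorder concept. Each maximal span yields one annotation
#' per disorder concept carrying the term; with `wsd = TRUE` a single
#' concept per span is kept (see [disambiguate()]).
#'
#' @param field_name One of `"condition"`, `"public_title"`,
#'   `"scientific_title"`.
#' @param text The field text.
#' @param lexicon A `gbd_lexicon`.
#' @param wsd Keep a single concept per span (word-sense disambiguation)?
#' @return Data frame with columns `field`, `start`, `end` (0-based
#'   half-open character span in the original text), `matched_text`, `cui`,
#'   ordered by span start.
#' @export
annotate <- function(field_name, text, lexicon, wsd = FALSE) {
  stopifnot(inherits(lexicon, "gbd_lexicon"))
  field_name <- match.arg(field_name, .trial_fields)
  empty <- data.frame(field = character(0), start = integer(0),
                      end = integer(0), matched_text = character(0),
                      cui = character(0), stringsAsFactors = FALSE)
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    return(empty)
  }
  toks <- .tokenize_with_spans(text)
  n <- nrow(toks)
  if (n == 0L) return(empty)
  index <- lexicon$.term_index
  maxlen <- lexicon$.max_term_tokens
  disorder <- lexicon$.disorder

  out <- list()
  i <- 1L
  while (i <= n) {
    hit_cuis <- NULL
    hit_len <- 0L
    for (len in seq.int(min(maxlen, n - i + 1L), 1L)) {
      key <- paste(toks$token[i:(i + len - 1L)], collapse = " ")
      cuis <- index[[key]]
      if (!is.null(cuis)) {
        cuis <- cuis[disorder[cuis]]
        if (length(cuis) > 0L) {
          hit_cuis <- sort(cuis)
          hit_len <- len
          break
        }
      }
    }
    if (hit_len > 0L) {
      start0 <- toks$start[i] - 1L                 # 0-based
      end0 <- toks$end[i + hit_len - 1L]           # half-open
      matched <- substring(text, start0 + 1L, end0)
      out[[length(out) + 1L]] <- data.frame(
        field = field_name, start = start0, end = end0,
        matched_text = matched, cui = hit_cuis, stringsAsFactors = FALSE)
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) return(empty)
  ann <- do.call(rbind, out)
  if (wsd) {
    spans <- split(seq_len(nrow(ann)), paste(ann$start, ann$end))
    keep <- vapply(spans, function(rows) {
      rows[.disambiguate_rows(ann[rows, , drop = FALSE], lexicon)]
    }, integer(1))
    ann <- ann[sort(unname(keep)), , drop = FALSE]
  }
  ann <- ann[order(ann$start, ann$cui), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

# Index (within the span group) of the concept to keep.
.disambiguate_rows <- function(group, lexicon) {
  if (nrow(group) == 1L) return(1L)
  matched <- paste(normalize_text(group$matched_text[1L]), collapse = " ")
  names <- vapply(group$cui, function(cui) {
    paste(normalize_text(lexicon$.preferred[[cui]]), collapse = " ")
  }, character(1))
  sims <- vapply(names, function(nm) .string_similarity(matched, nm),
                 numeric(1))
  best <- which(sims == max(sims))
  best[order(group$cui[best])][1L]  # tie -> lexicographically smallest cui
}

# Normalized similarity in [0, 1] from Levenshtein distance.
.string_similarity <- function(a, b) {
  if (!nzchar(a) && !nzchar(b)) return(1)
  1 - utils::adist(a, b)[1L, 1L] / max(nchar(a), nchar(b))
}

#' Select a single concept for a span
#'
#' Given several annotations sharing one span, keeps the concept whose
#' preferred name is most similar to the matched text (normalized
#' Levenshtein similarity); ties are broken by the lexicographically
#' smallest concept id. This is the deterministic word-sense disambiguation
#' rule used when `wsd = TRUE`.
#'
#' @param annotations Data frame of annotations sharing one span (>= 1 row).
#' @param lexicon A `gbd_lexicon`.
#' @return The single kept annotation row.
#' @export
disambiguate <- function(annotations, lexicon) {
  stopifnot(inherits(lexicon, "gbd_lexicon"))
  if (!is.data.frame(annotations) || nrow(annotations) == 0L) {
    stop("disambiguate() requires at least one annotation", call. = FALSE)
  }
  if (length(unique(paste(annotations$start, annotations$end))) != 1L) {
    stop("disambiguate() requires annotations sharing a single span",
         call. = FALSE)
  }
  keep <- .disambiguate_rows(annotations, lexicon)
  out <- annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read externally produced annotations
#'
#' Ingests a JSON array of objects `{trial_id, field, start, end, text,
#' cui}` (0-based half-open spans), e.g. converted output of a full-scale
#' concept recognizer, for use in place of the built-in matcher.
#'
#' @param path JSON file path.
#' @param trials Optional data frame of trial records; when given, each
#'   annotation's `text` is checked against the field substring at its span.
#' @return Named list: `trial_id` -> data frame of annotations in the layout
#'   of [annotate()].
#' @export
read_annotations <- function(path, trials = NULL) {
  records <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(records) == 0L) return(stats::setNames(list(), character(0)))
  required <- c("trial_id", "field", "start", "end", "text", "cui")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop(sprintf("annotation file missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (i in seq_len(nrow(records))) {
    if (!(records$field[i] %in% .trial_fields)) {
      stop(sprintf("annotation record %d: unknown field '%s'",
                   i, records$field[i]), call. = FALSE)
    }
    if (records$end[i] <= records$start[i]) {
      stop(sprintf("annotation record %d: empty or inverted span [%d, %d)",
                   i, records$start[i], records$end[i]), call. = FALSE)
    }
    if (!is.null(trials)) {
      j <- match(records$trial_id[i], trials$trial_id)
      if (is.na(j)) {
        stop(sprintf("annotation record %d: unknown trial '%s'",
                     i, records$trial_id[i]), call. = FALSE)
      }
      fragment <- substring(trials[[records$field[i]]][j],
                            records$start[i] + 1L, records$end[i])
      if (!identical(fragment, records$text[i])) {
        stop(sprintf(
          "annotation record %d: text '%s' does not match span substring '%s'",
          i, records$text[i], fragment), call. = FALSE)
      }
    }
  }
  ann <- data.frame(field = records$field,
                    start = as.integer(records$start),
                    end = as.integer(records$end),
                    matched_text = records$text,
                    cui = records$cui, stringsAsFactors = FALSE)
  split(ann, records$trial_id)
}
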