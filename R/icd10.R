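#' @title ICD-10 codes and blocks
#' @description Lightweight S3 representations of three- and four-character
#'   ICD-10 codes ("M16", "M16.9") and of contiguous blocks of such codes
#'   ("F30-F39.9"), with a total order and deterministic block expansion.
#'   These are the atoms over which GBD groupings are defined.
#' @name icd10
NULL

# Integer sort key. Each three-character code owns 11 slots: the bare code
# (minor absent) followed by its ten one-decimal extensions .0-.9, so that
# "M16" < "M16.0" < ... < "M16.9" < "M17".
.icd10_key <- function(letter, major, minor) {
  li <- match(letter, LETTERS) - 1L
  mpos <- ifelse(is.na(minor), 0L, minor + 1L)
  li * 1100L + major * 11L + mpos
}

.icd10_from_key <- function(key) {
  li <- key %/% 1100L
  rest <- key %% 1100L
  major <- rest %/% 11L
  mpos <- rest %% 11L
  minor <- ifelse(mpos == 0L, NA_integer_, mpos - 1L)
  list(letter = LETTERS[li + 1L], major = major, minor = minor)
}

.new_icd10_code <- function(letter, major, minor = NA_integer_) {
  structure(
    list(letter = letter, major = as.integer(major),
         minor = as.integer(minor)),
    class = "icd10_code"
  )
}

.new_icd10_block <- function(start, end) {
  structure(list(start = start, end = end), class = "icd10_block")
}

#' Parse an ICD-10 code or block
#'
#' Accepts a single three- or four-character ICD-10 code (e.g. `"M16"`,
#' `"M16.9"`) or a block written as two codes joined by a dash (e.g.
#' `"F30-F39.9"`). Hyphen, en-dash and em-dash are all accepted as the block
#' separator; letter case and surrounding whitespace are normalized.
#'
#' @param text A single character string.
#' @return An object of class `icd10_code` or `icd10_block`.
#' @examples
#' parse_icd10("M16.9")
#' parse_icd10("F30-F39.9")
#' @export
parse_icd10 <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("parse_icd10() expects a single character string", call. = FALSE)
  }
  raw <- text
  text <- toupper(trimws(text))
  # normalize dash dialects (en-dash U+2013, em-dash U+2014, minus U+2212)
  text <- gsub("[–—−]", "-", text)
  if (!nzchar(text)) {
    stop("parse_icd10(): empty ICD-10 specification", call. = FALSE)
  }
  parts <- strsplit(text, "-", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  if (length(parts) == 1L) {
    return(.parse_icd10_single(parts[1L], raw))
  }
  if (length(parts) != 2L || !all(nzchar(parts))) {
    stop(sprintf("parse_icd10(): malformed block specification '%s'", raw),
         call. = FALSE)
  }
  start <- .parse_icd10_single(parts[1L], raw)
  end <- .parse_icd10_single(parts[2L], raw)
  if (icd10_key(start) > icd10_key(end)) {
    stop(sprintf("parse_icd10(): block start exceeds end in '%s'", raw),
         call. = FALSE)
  }
  .new_icd10_block(start, end)
}

.parse_icd10_single <- function(text, raw = text) {
  m <- regmatches(text, regexec("^([A-Z])([0-9]{2})(?:\\.([0-9]))?$", text))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("parse_icd10(): malformed ICD-10 code '%s' (in '%s')",
                 text, raw), call. = FALSE)
  }
  minor <- if (is.na(m[4L]) || !nzchar(m[4L])) NA_integer_ else as.integer(m[4L])
  .new_icd10_code(m[2L], as.integer(m[3L]), minor)
}

#' @export
format.icd10_code <- function(x, ...) {
  if (is.na(x$minor)) {
    sprintf("%s%02d", x$letter, x$major)
  } else {
    sprintf("%s%02d.%d", x$letter, x$major, x$minor)
  }
}

#' @export
format.icd10_block <- function(x, ...) {
  paste0(format(x$start), "-", format(x$end))
}

#' @export
print.icd10_code <- function(x, ...) {
  cat("<ICD-10 code>", format(x), "\n")
  invisible(x)
}

#' @export
print.icd10_block <- function(x, ...) {
  cat("<ICD-10 block>", format(x), "\n")
  invisible(x)
}

#' Total-order sort key of an ICD-10 code
#'
#' Orders by letter, then two-digit major, then decimal minor, with an absent
#' minor ranked immediately before `.0`.
#'
#' @param code An `icd10_code`.
#' @return An integer scalar; larger means later in ICD-10 order.
#' @export
icd10_key <- function(code) {
  stopifnot(inherits(code, "icd10_code"))
  .icd10_key(code$letter, code$major, code$minor)
}

#' Expand an ICD-10 block into its constituent codes
#'
#' Enumerates, in ICD-10 order, every three-character code together with its
#' ten one-decimal extensions lying between the block endpoints (inclusive,
#' clipped exactly at both ends). A block ending at a bare three-character
#' code stops at that code itself; one ending at `.9` covers all extensions
#' of the final three-character code. If `universe` is supplied the
#' enumeration is intersected with it, preserving order.
#'
#' @param block An `icd10_block` (or a string parseable as one).
#' @param universe Optional character vector of canonical code strings to
#'   intersect with.
#' @return Character vector of canonical code strings.
#' @examples
#' length(expand_block(parse_icd10("F30-F39.9")))  # 110
#' @export
expand_block <- function(block, universe = NULL) {
  if (is.character(block)) block <- parse_icd10(block)
  if (inherits(block, "icd10_code")) block <- .new_icd10_block(block, block)
  stopifnot(inherits(block, "icd10_block"))
  k1 <- icd10_key(block$start)
  k2 <- icd10_key(block$end)
  keys <- seq.int(k1, k2)
  parts <- .icd10_from_key(keys)
  out <- ifelse(
    is.na(parts$minor),
    sprintf("%s%02d", parts$letter, parts$major),
    sprintf("%s%02d.%d", parts$letter, parts$major, parts$minor)
  )
  if (!is.null(universe)) out <- out[out %in% universe]
  out
}

# Canonical string for a code or block spec.
.icd10_canonical <- function(spec) {
  if (inherits(spec, "icd10_code") || inherits(spec, "icd10_block")) {
    format(spec)
  } else {
    format(parse_icd10(spec))
  }
}

# Three-character parent of a canonical code string ("M16.9" -> "M16").
.icd10_parent <- function(code_str) {
  sub("\\.[0-9]$", "", code_str)
}

# TRUE for four-character (one-decimal) canonical code strings.
.icd10_has_minor <- function(code_str) {
  grepl("\\.", code_str, fixed = TRUE)
}
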