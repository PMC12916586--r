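#' Parse an HLA allele name
#'
#' HLA alleles are named `LOCUS*F1:F2:F3:F4` with one to four numeric fields
#' and an optional single-letter expression suffix (e.g. `"B*39:01:01L"`,
#' where `L` marks low cell-surface expression).  Three fields correspond to
#' the "six-digit" resolution produced by full-gene NGS typing.
#'
#' Alleles are compared as exact strings at their given resolution; the
#' parser never truncates or rolls names up to two-field ("four-digit")
#' groups, because closely related alleles such as `DPB1*02:01:01` and
#' `DPB1*02:01:02` can carry opposite association signals.
#'
#' @param x character vector of allele names, e.g. `"A*02:01:01"`.
#' @return For `parse_allele`, a list of `hla_allele` objects (a single
#'   object if `length(x) == 1`), each with components `locus`, `fields`
#'   (character vector, zero-padding preserved), `suffix` (`""` if absent)
#'   and `raw`.
#' @examples
#' a <- parse_allele("B*39:01:01L")
#' a$locus          # "B"
#' a$fields         # "39" "01" "01"
#' a$suffix         # "L"
#' format(a)        # round-trips to "B*39:01:01L"
#' @export
parse_allele <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  out <- lapply(x, parse_allele_one)
  if (length(out) == 1L) out[[1]] else out
}

parse_allele_one <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    stop("empty allele name", call. = FALSE)
  }
  m <- regexec("^([A-Z0-9]+)\\*([0-9]+(?::[0-9]+){0,3})([A-Za-z]?)$", s)
  g <- regmatches(s, m)[[1]]
  if (length(g) == 0L) {
    stop(sprintf("malformed HLA allele name: '%s'", s), call. = FALSE)
  }
  structure(
    list(
      locus  = g[2],
      fields = strsplit(g[3], ":", fixed = TRUE)[[1]],
      suffix = g[4],
      raw    = s
    ),
    class = "hla_allele"
  )
}

#' @export
format.hla_allele <- function(x, ...) {
  paste0(x$locus, "*", paste(x$fields, collapse = ":"), x$suffix)
}

#' @export
print.hla_allele <- function(x, ...) {
  cat("<hla_allele> ", format(x), "  (", length(x$fields),
      "-field resolution)\n", sep = "")
  invisible(x)
}

#' @export
as.character.hla_allele <- function(x, ...) format(x)

#' Locus of an allele name
#'
#' @param x character vector of allele names.
#' @return character vector of locus tokens (the part before `*`).
#' @export
allele_locus <- function(x) {
  vapply(x, function(s) parse_allele_one(s)$locus, character(1),
         USE.NAMES = FALSE)
}

#' Resolution (number of colon-delimited fields) of an allele name
#'
#' @param x character vector of allele names.
#' @return integer vector.
#' @export
allele_resolution <- function(x) {
  vapply(x, function(s) length(parse_allele_one(s)$fields), integer(1),
         USE.NAMES = FALSE)
}

#' Truncate allele names to a lower field resolution
#'
#' Optional rollup transform (default behaviour everywhere else in the
#' package is *no* rollup).  The expression suffix is dropped on truncation
#' since it qualifies the full-resolution name only.
#'
#' @param x character vector of allele names.
#' @param fields target number of fields (1--4).
#' @return character vector of truncated names; names already at or below
#'   the target resolution are returned unchanged.
#' @export
allele_rollup <- function(x, fields = 2L) {
  stopifnot(fields >= 1L, fields <= 4L)
  vapply(x, function(s) {
    a <- parse_allele_one(s)
    if (length(a$fields) <= fields) return(s)
    paste0(a$locus, "*", paste(a$fields[seq_len(fields)], collapse = ":"))
  }, character(1), USE.NAMES = FALSE)
}

# canonical chromosomal order of the loci handled by this package
#' Supported HLA loci in chromosomal order
#'
#' Class I (A, C, B) and Class II (DRB1, DQA1, DQB1, DPB1) loci, ordered by
#' physical position on chromosome 6p21.  Used for column ordering in
#' genotype tables and axis ordering in LD matrices.
#' @return character vector of locus names.
#' @export
hla_loci <- function() c("A", "C", "B", "DRB1", "DQA1", "DQB1", "DPB1")
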