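#' Parse structured allele names
#'
#' Allele names follow the HLA-style nomenclature used for MIC genes:
#' `GENE*FF(:SF)*` with colon-separated numeric fields, an optional trailing
#' `N` (null allele) and an optional trailing `#` marking an ambiguity-group
#' representative (display names only).
#'
#' @param x character vector of allele names.
#' @return A data.frame with one row per name: `gene`, `fields` (the colon
#'   part, as printed), `f1`..`f4` (numeric field values, `NA` where absent),
#'   `null_suffix` (logical), `hash` (logical) and `name` (the input).
#' @examples
#' parse_allele_name(c("MICA*008:01", "MICB*009N", "MICB*005#"))
#' @export
parse_allele_name <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^([A-Za-z][A-Za-z0-9-]*)\\*([0-9]+(?::[0-9]+)*)(N?)(#?)$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed allele name(s): ", paste(x[bad], collapse = ", "))
  }
  gene <- vapply(m, `[[`, "", 2L)
  fields <- vapply(m, `[[`, "", 3L)
  nsuf <- vapply(m, `[[`, "", 4L) == "N"
  hash <- vapply(m, `[[`, "", 5L) == "#"
  fl <- strsplit(fields, ":", fixed = TRUE)
  fmat <- t(vapply(fl, function(f) {
    v <- suppressWarnings(as.integer(f))
    length(v) <- 4L
    v
  }, integer(4)))
  out <- data.frame(
    name = x, gene = gene, fields = fields,
    f1 = fmat[, 1L], f2 = fmat[, 2L], f3 = fmat[, 3L], f4 = fmat[, 4L],
    null_suffix = nsuf, hash = hash,
    stringsAsFactors = FALSE
  )
  out
}

#' Order allele names
#'
#' Deterministic ordering used throughout for representative selection and
#' stable output: by gene, then numerically field by field; a null-suffixed
#' (`N`) allele sorts directly after its numeric equal; a trailing `#` is
#' ignored for ordering.
#'
#' @param x character vector of allele names.
#' @return An integer permutation, as from [order()].
#' @examples
#' x <- c("MICA*010", "MICA*008:04", "MICA*008:01", "MICA*064N")
#' x[allele_name_order(x)]
#' @export
allele_name_order <- function(x) {
  p <- parse_allele_name(sub("#$", "", as.character(x)))
  mi <- function(v) ifelse(is.na(v), -1L, v)
  order(p$gene, mi(p$f1), mi(p$f2), mi(p$f3), mi(p$f4), p$null_suffix)
}

#' @rdname allele_name_order
#' @export
sort_allele_names <- function(x) x[allele_name_order(x)]

#' Protein-level (first-field) designation of an allele name
#'
#' Truncates an allele name to its gene-qualified first field, e.g.
#' `MICA*008:04` becomes `MICA*008`. A trailing `N` is preserved only for
#' single-field names (e.g. `MICB*009N`), where it is part of the
#' protein-level designation.
#'
#' @param x character vector of allele names.
#' @return Character vector of first-field names.
#' @examples
#' first_field(c("MICA*008:01", "MICA*008", "MICB*009N"))
#' @export
first_field <- function(x) {
  p <- parse_allele_name(sub("#$", "", as.character(x)))
  one_field <- !grepl(":", p$fields, fixed = TRUE)
  paste0(p$gene, "*", sub(":.*$", "", p$fields),
         ifelse(p$null_suffix & one_field, "N", ""))
}
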