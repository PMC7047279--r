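#' Emit a Genotype List (GL) string
#'
#' `+` joins the two alleles of one genotype; `|` separates alternative
#' genotypes that the assay cannot distinguish (phasing ambiguity). Pairs
#' are sorted deterministically: within a pair by allele name, across pairs
#' by first then second member (see [allele_name_order()]), so emission is
#' canonical and `parse_gl(emit_gl(x))` recovers `x`.
#'
#' @param pairs a list of length-2 character vectors (allele or group
#'   display names, `#` allowed), or a 2-column character matrix.
#' @return A single GL string.
#' @examples
#' emit_gl(list(c("MICB*005#", "MICB*002"), c("MICB*019", "MICB*018")))
#' @export
emit_gl <- function(pairs) {
  if (is.matrix(pairs)) pairs <- lapply(seq_len(nrow(pairs)), function(i) pairs[i, ])
  if (!length(pairs)) stop("empty pair set")
  pairs <- lapply(pairs, function(p) {
    if (length(p) != 2L) stop("each genotype must have exactly two alleles")
    p[allele_name_order(p)]
  })
  first <- vapply(pairs, `[[`, "", 1L)
  second <- vapply(pairs, `[[`, "", 2L)
  pairs <- pairs[order(rank_key(first), rank_key(second))]
  pairs <- pairs[!duplicated(vapply(pairs, paste, "", collapse = "+"))]
  paste(vapply(pairs, paste, "", collapse = "+"), collapse = "|")
}

rank_key <- function(x) {
  u <- unique(x)
  u_sorted <- u[allele_name_order(u)]
  match(x, u_sorted)
}

#' Parse a GL string
#'
#' Inverse of [emit_gl()]. Accepts the `+`/`|` subset of the GL grammar used
#' for single-locus unphased genotypes.
#'
#' @param gl a single GL string.
#' @return List of length-2 character vectors (one per alternative
#'   genotype), in canonical order.
#' @examples
#' parse_gl("MICB*002+MICB*005#|MICB*018+MICB*019")
#' @export
parse_gl <- function(gl) {
  stopifnot(is.character(gl), length(gl) == 1L)
  if (!nzchar(gl)) stop("GL parse error at position 1: empty string")
  tok_re <- "^[A-Za-z][A-Za-z0-9-]*\\*[0-9]+(:[0-9]+)*N?#?$"
  pos <- 1L
  pairs <- list()
  for (gt in strsplit(gl, "|", fixed = TRUE)[[1L]]) {
    alleles <- strsplit(gt, "+", fixed = TRUE)[[1L]]
    if (length(alleles) != 2L) {
      stop(sprintf("GL parse error at position %d: genotype '%s' must have exactly 2 alleles",
                   pos, gt))
    }
    for (al in alleles) {
      if (!grepl(tok_re, al)) {
        stop(sprintf("GL parse error at position %d: bad allele name '%s'", pos, al))
      }
      pos <- pos + nchar(al) + 1L
    }
    pairs[[length(pairs) + 1L]] <- alleles[allele_name_order(alleles)]
  }
  first <- vapply(pairs, `[[`, "", 1L)
  second <- vapply(pairs, `[[`, "", 2L)
  pairs[order(rank_key(first), rank_key(second))]
}
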