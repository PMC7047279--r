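#' Construct a frequency prior
#'
#' A per-gene map from ambiguity-group display names to allele frequencies,
#' used to rank alternative genotype explanations under Hardy-Weinberg
#' equilibrium. Groups absent from the map receive the pseudo-frequency
#' `floor` (> 0), so no explanation is ever excluded with probability zero.
#'
#' @param frequencies named list, gene -> named numeric vector of
#'   frequencies in `[0, 1]` (need not sum exactly to 1, but must not exceed
#'   1 beyond rounding).
#' @param floor pseudo-frequency for unlisted groups.
#' @return An object of class `frequency_prior`.
#' @examples
#' frequency_prior(list(MICB = c("MICB*005#" = 0.439, "MICB*002" = 0.189)))
#' @export
frequency_prior <- function(frequencies, floor = 1e-5) {
  stopifnot(is.list(frequencies), floor > 0)
  for (g in names(frequencies)) {
    f <- frequencies[[g]]
    if (is.null(names(f)) || any(is.na(f)) || any(f < 0)) {
      stop("frequencies for gene ", g, " must be a named non-negative vector")
    }
    if (sum(f) > 1 + 1e-9) stop("frequencies for gene ", g, " sum to more than 1")
  }
  structure(list(frequencies = frequencies, floor = floor),
            class = "frequency_prior")
}

prior_freq <- function(prior, gene, groups) {
  f <- prior$frequencies[[gene]]
  out <- unname(f[groups])
  out[is.na(out)] <- prior$floor
  out
}

#' Hardy-Weinberg genotype probability
#'
#' Probability of an unordered allele-group pair under Hardy-Weinberg
#' equilibrium: `2 * f1 * f2` for heterozygous pairs, `f^2` for homozygous
#' pairs.
#'
#' @param pair length-2 character vector of group display names, or a list
#'   of such pairs (vectorized).
#' @param prior a [frequency_prior()].
#' @param gene gene the pair belongs to.
#' @return Numeric vector of probabilities.
#' @examples
#' pr <- frequency_prior(list(MICB = c("MICB*002" = 0.189, "MICB*005#" = 0.439)))
#' hwe_probability(c("MICB*002", "MICB*005#"), pr, "MICB")
#' @export
hwe_probability <- function(pair, prior, gene) {
  if (!is.list(pair)) pair <- list(pair)
  vapply(pair, function(p) {
    stopifnot(length(p) == 2L)
    f <- prior_freq(prior, gene, p)
    if (any(!is.finite(f)) || any(f < 0)) stop("invalid frequency for pair ", paste(p, collapse = "+"))
    if (p[1L] == p[2L]) f[1L]^2 else 2 * f[1L] * f[2L]
  }, numeric(1))
}

#' Statistically resolve a phasing ambiguity
#'
#' Ranks the alternative genotype explanations of a phase-ambiguous call by
#' Hardy-Weinberg probability under `prior` and discards alternatives whose
#' probability ratio to the best explanation falls below `1/odds_threshold`.
#' If exactly one explanation survives, the call is resolved and
#' `expected_error` records the normalized probability mass of the
#' discarded alternatives (the chance the discarded option was the truth,
#' under the prior). If several survive (or every candidate sits at the
#' frequency floor), the call is left unresolved with all survivors
#' retained.
#'
#' @param pairs list of length-2 character vectors (candidate genotypes), or
#'   a `genotype_call` from [enumerate_genotypes()].
#' @param prior a [frequency_prior()].
#' @param gene gene name (taken from the call if omitted).
#' @param odds_threshold minimum probability ratio for exclusion (default
#'   1000: an alternative is dropped only when it is at least 1000-fold less
#'   likely than the best explanation).
#' @param probabilities optional numeric vector of externally computed
#'   per-pair probabilities to use instead of HWE under `prior`.
#' @return An object of class `resolved_call`: list with `pairs`,
#'   `probabilities` (normalized), `retained` (indices), `discarded`,
#'   `resolved` (logical), `chosen` (pair or `NULL`), `expected_error`, and
#'   `gl` (GL string of the retained set).
#' @examples
#' rc <- resolve_phasing(
#'   list(c("MICB*002", "MICB*005#"), c("MICB*018", "MICB*019")),
#'   probabilities = c(0.039, 1.9e-8), odds_threshold = 1000)
#' rc$chosen
#' rc$expected_error
#' @export
resolve_phasing <- function(pairs, prior = NULL, gene = NULL,
                            odds_threshold = 1000, probabilities = NULL) {
  if (inherits(pairs, "genotype_call")) {
    if (is.null(gene)) gene <- pairs$gene
    pairs <- pairs$pairs
  }
  stopifnot(length(pairs) >= 1L)
  all_floor <- FALSE
  if (is.null(probabilities)) {
    if (is.null(prior) || is.null(gene)) stop("need a prior and gene (or explicit probabilities)")
    probabilities <- hwe_probability(pairs, prior, gene)
    known <- vapply(pairs, function(p)
      any(p %in% names(prior$frequencies[[gene]])), logical(1))
    all_floor <- !any(known)
  }
  if (length(probabilities) != length(pairs)) stop("one probability per pair required")
  norm <- probabilities / sum(probabilities)
  best <- max(probabilities)
  retained <- which(probabilities >= best / odds_threshold)
  if (all_floor) {
    retained <- seq_along(pairs)
    warning("all candidate pairs at floor frequency; ambiguity left unresolved")
  }
  discarded <- setdiff(seq_along(pairs), retained)
  resolved <- length(retained) == 1L && length(pairs) > 1L
  structure(list(
    pairs = pairs,
    probabilities = norm,
    raw_probabilities = probabilities,
    retained = retained,
    discarded = discarded,
    resolved = resolved,
    chosen = if (length(retained) == 1L) pairs[[retained]] else NULL,
    expected_error = sum(norm[discarded]),
    gl = emit_gl(pairs[retained])
  ), class = "resolved_call")
}

#' @export
print.resolved_call <- function(x, ...) {
  cat("resolved_call:", x$gl, "\n")
  cat(sprintf("  %d candidate(s), %d retained; expected_error = %.3g\n",
              length(x$pairs), length(x$retained), x$expected_error))
  invisible(x)
}
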