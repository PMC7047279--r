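usable_rows <- function(results, gl_col = "gl") {
  !is.na(results[[gl_col]]) & !results$novel &
    !grepl("low_coverage_retest", results$flags)
}

count_pairs <- function(pairs_list, weights, groups) {
  counts <- setNames(numeric(length(groups)), groups)
  for (i in seq_along(pairs_list)) {
    p <- pairs_list[[i]]
    counts[p[1L]] <- counts[p[1L]] + weights[i]
    counts[p[2L]] <- counts[p[2L]] + weights[i]
  }
  counts
}

#' Provisional allele-group frequencies from unambiguous results
#'
#' Counts alleles over the unambiguously typed samples only (a homozygous
#' result counts as two alleles) and converts to frequencies; groups never
#' seen receive the floor pseudo-frequency. This is the prior used to rank
#' and allocate ambiguous genotypes.
#'
#' @param results a [type_cohort()] data.frame.
#' @param floor pseudo-frequency for unseen groups.
#' @return A [frequency_prior()].
#' @examples
#' r <- data.frame(sample = 1:3, gene = "MICA",
#'   gl = c("MICA*001+MICA*001", "MICA*001+MICA*002", "MICA*002+MICA*004"),
#'   flags = "", novel = FALSE, phase_ambiguous = FALSE)
#' provisional_frequencies(r)$frequencies
#' @export
provisional_frequencies <- function(results, floor = 1e-5) {
  freqs <- list()
  for (g in unique(results$gene)) {
    r <- results[results$gene == g & usable_rows(results) & !results$phase_ambiguous, ,
                 drop = FALSE]
    if (!nrow(r)) {
      stop("no unambiguous samples for gene ", g,
           "; supply an external prior instead")
    }
    ugl <- unique(r$gl)
    mult <- as.numeric(table(factor(r$gl, levels = ugl)))
    pairs <- lapply(ugl, function(gl) parse_gl(gl)[[1L]])
    groups <- sort_allele_names(unique(unlist(pairs)))
    counts <- count_pairs(pairs, mult, groups)
    freqs[[g]] <- counts / (2 * nrow(r))
  }
  frequency_prior(freqs, floor = floor)
}

#' Allele-group frequency table with fractional allocation of ambiguities
#'
#' Unambiguous samples (including, by default, phasing ambiguities already
#' resolved by [resolve_cohort()]) contribute integer allele counts; each
#' remaining ambiguous sample contributes two fractional counts split
#' across its candidate genotypes proportionally to their Hardy-Weinberg
#' probabilities under the prior. `mode = "em"` re-derives the prior from
#' the current table and repeats until the largest absolute frequency
#' change drops below `tol`; `mode = "single_pass"` performs exactly one
#' allocation pass (and equals the first EM iteration).
#'
#' @param results a [type_cohort()] data.frame, normally after
#'   [resolve_cohort()].
#' @param prior a [frequency_prior()], normally
#'   [provisional_frequencies()] of the same results.
#' @param mode `"single_pass"` or `"em"`.
#' @param tol EM convergence tolerance on frequencies.
#' @param max_iter maximum EM iterations.
#' @param resolved_as_unambiguous if `TRUE` (default), samples resolved by
#'   the odds threshold contribute integer counts to their chosen
#'   genotype; if `FALSE` they are allocated fractionally over the
#'   original candidate set.
#' @return A `frequency_table` data.frame: `gene`, `group`,
#'   `unambiguous_count`, `allocated_count`, `total_count`, `frequency`,
#'   with attributes `n_samples_used` (named per gene), `mode` and
#'   `iterations`. Per gene, total counts sum to twice the number of
#'   samples used and frequencies sum to 1.
#' @export
allocate_ambiguous <- function(results, prior, mode = c("single_pass", "em"),
                               tol = 1e-8, max_iter = 200L,
                               resolved_as_unambiguous = TRUE) {
  mode <- match.arg(mode)
  gl_col <- if (resolved_as_unambiguous && !is.null(results$gl_final)) "gl_final" else "gl"
  out <- list()
  n_used <- c()
  iters <- c()
  for (g in unique(results$gene)) {
    r <- results[results$gene == g & usable_rows(results, gl_col), , drop = FALSE]
    if (!nrow(r)) stop("no usable samples for gene ", g)
    gls <- r[[gl_col]]
    ugl <- unique(gls)
    mult <- as.numeric(table(factor(gls, levels = ugl)))
    pair_sets <- lapply(ugl, parse_gl)
    single <- vapply(pair_sets, length, 1L) == 1L
    groups <- sort_allele_names(unique(c(unlist(pair_sets),
                                         names(prior$frequencies[[g]]))))
    unamb_counts <- count_pairs(lapply(pair_sets[single], `[[`, 1L),
                                mult[single], groups)
    f <- prior_freq(prior, g, groups)
    names(f) <- groups
    it <- 0L
    repeat {
      it <- it + 1L
      pr_it <- frequency_prior(setNames(list(f[f > 0]), g), floor = prior$floor)
      alloc_counts <- setNames(numeric(length(groups)), groups)
      for (k in which(!single)) {
        w <- hwe_probability(pair_sets[[k]], pr_it, g)
        w <- w / sum(w)
        alloc_counts <- alloc_counts +
          count_pairs(pair_sets[[k]], w * mult[k], groups)
      }
      total <- unamb_counts + alloc_counts
      f_new <- total / sum(total)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (mode == "single_pass" || delta < tol) break
      if (it >= max_iter) {
        stop("EM did not converge after ", max_iter,
             " iterations (last max change ", signif(delta, 3), ")")
      }
    }
    stopifnot(abs(sum(total) - 2 * nrow(r)) < 1e-6)
    out[[g]] <- data.frame(gene = g, group = groups,
                           unambiguous_count = unname(unamb_counts),
                           allocated_count = unname(alloc_counts),
                           total_count = unname(total),
                           frequency = unname(f), stringsAsFactors = FALSE)
    n_used[g] <- nrow(r)
    iters[g] <- it
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  structure(tab, n_samples_used = n_used, mode = mode, iterations = iters,
            class = c("frequency_table", "data.frame"))
}

#' Estimate cohort frequencies from typing results (one call)
#'
#' Convenience wrapper: derives the provisional prior from the unambiguous
#' samples, then allocates the ambiguous ones.
#'
#' @inheritParams allocate_ambiguous
#' @param floor floor pseudo-frequency for the prior.
#' @return A `frequency_table` (see [allocate_ambiguous()]) with the prior
#'   attached as attribute `prior`.
#' @export
estimate_frequencies <- function(results, mode = "single_pass", tol = 1e-8,
                                 floor = 1e-5, resolved_as_unambiguous = TRUE) {
  prior <- provisional_frequencies(results, floor = floor)
  tab <- allocate_ambiguous(results, prior, mode = mode, tol = tol,
                            resolved_as_unambiguous = resolved_as_unambiguous)
  attr(tab, "prior") <- prior
  tab
}

#' Audit rare allele-group calls
#'
#' Lists every group observed fewer than `threshold` times. A rare group is
#' `confirmed` when it was seen in at least two distinct verified samples
#' (the `verified` column of `results`; all samples count as verified when
#' the column is absent), otherwise `needs_reconfirmation`.
#'
#' @param table a `frequency_table`.
#' @param results the [type_cohort()] data.frame the table was computed
#'   from (optionally with a logical `verified` column).
#' @param threshold count below which a group is audited (default 50).
#' @return data.frame: `gene`, `group`, `total_count`,
#'   `n_distinct_samples`, `status`.
#' @export
rare_allele_audit <- function(table, results, threshold = 50) {
  if (is.null(results$verified)) results$verified <- TRUE
  gl_col <- if (!is.null(results$gl_final)) "gl_final" else "gl"
  rows <- list()
  rare <- table[table$total_count < threshold, , drop = FALSE]
  for (i in seq_len(nrow(rare))) {
    g <- rare$gene[i]; grp <- rare$group[i]
    r <- results[results$gene == g & usable_rows(results, gl_col) & results$verified, ,
                 drop = FALSE]
    seen <- vapply(r[[gl_col]], function(gl) grp %in% unlist(parse_gl(gl)), logical(1))
    nds <- length(unique(r$sample[seen]))
    rows[[i]] <- data.frame(gene = g, group = grp,
                            total_count = rare$total_count[i],
                            n_distinct_samples = nds,
                            status = if (nds >= 2L) "confirmed" else "needs_reconfirmation",
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), group = character(0),
                      total_count = numeric(0), n_distinct_samples = integer(0),
                      status = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a frequency table as per-gene TSV (descending, with cumulative)
#' @param table a `frequency_table`.
#' @param path output TSV.
#' @param metadata optional named character vector echoed as `#` header
#'   lines.
#' @return `path` invisibly.
#' @export
write_frequency_table <- function(table, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata)) {
    writeLines(sprintf("# %s: %s", names(metadata), metadata), con)
  }
  tabs <- lapply(split(as.data.frame(table), table$gene), function(t) {
    t <- t[order(-t$frequency, rank_key(t$group)), , drop = FALSE]
    t$cumulative <- cumsum(t$frequency)
    t
  })
  full <- do.call(rbind, tabs)
  write.table(format(full, digits = 8, scientific = FALSE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
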