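#' Run the closed simulation-to-estimation loop
#'
#' Draws a Hardy-Weinberg cohort from configured truth frequencies,
#' simulates and types the reads, resolves phasing ambiguities against the
#' provisional (unambiguous-sample) prior, estimates allele-group
#' frequencies with fractional allocation, and compares the estimates with
#' the simulation truth.
#'
#' @param genes genes to simulate (`"MICA"`, `"MICB"` or both).
#' @param n_samples cohort size.
#' @param seed integer seed.
#' @param depth read pairs per amplicon per sample.
#' @param error_rate per-base substitution error rate.
#' @param novel_rate per-sample novel-allele injection probability.
#' @param db allele database (default: the packaged synthetic German
#'   reference restricted to `genes`).
#' @param panel amplicon panel.
#' @param frequencies truth frequencies (default: German reference values).
#' @param odds_threshold phasing-resolution threshold.
#' @param mode frequency-allocation mode.
#' @param engine `"reads"` or `"exact"` (see [type_cohort()]).
#' @param params a [typing_params()].
#' @return List of class `closed_loop`: `cohort`, `results` (resolved),
#'   `prior`, `table` (frequency estimates), `recovery` (data.frame with
#'   per-group truth vs estimate, binomial SE and `within_3se`), and
#'   `summary` ([summarize_cohort()]).
#' @examples
#' \donttest{
#' loop <- run_closed_loop("MICB", n_samples = 500, seed = 7, depth = 50)
#' loop$recovery
#' }
#' @export
run_closed_loop <- function(genes = c("MICA", "MICB"), n_samples = 1000L,
                            seed = 1L, depth = 100L, error_rate = 0.01,
                            novel_rate = 0, db = NULL,
                            panel = default_panel(), frequencies = NULL,
                            odds_threshold = 1000, mode = "single_pass",
                            engine = "reads", params = typing_params()) {
  genes <- match.arg(genes, c("MICA", "MICB"), several.ok = TRUE)
  if (is.null(db)) db <- make_german_reference_db(genes = genes)
  config <- simulation_config(seed = seed, n_samples = n_samples,
                              genes = genes, frequencies = frequencies,
                              depth = depth, error_rate = error_rate,
                              novel_rate = novel_rate)
  cohort <- sample_cohort(db, config, panel)
  results <- type_cohort(db, panel, cohort, params = params, engine = engine)
  prior <- provisional_frequencies(results)
  results <- resolve_cohort(results, prior, odds_threshold = odds_threshold)
  table <- allocate_ambiguous(results, prior, mode = mode)
  recovery <- recovery_table(table, config)
  structure(list(db = db, cohort = cohort, results = results, prior = prior,
                 table = table, recovery = recovery,
                 summary = summarize_cohort(results), config = config),
            class = "closed_loop")
}

#' Compare estimated frequencies with simulation truth
#'
#' @param table a `frequency_table`.
#' @param config the [simulation_config()] that generated the cohort.
#' @return data.frame: `gene`, `group`, `truth`, `estimate`, `se`
#'   (binomial SE of the truth at the number of alleles used) and
#'   `within_3se`.
#' @export
recovery_table <- function(table, config) {
  n_used <- attr(table, "n_samples_used")
  rows <- list()
  for (g in unique(table$gene)) {
    truth <- renormalize_frequencies(config$frequencies[[g]])
    t <- table[table$gene == g, , drop = FALSE]
    est <- setNames(t$frequency, t$group)
    for (grp in names(truth)) {
      f <- truth[[grp]]
      se <- sqrt(f * (1 - f) / (2 * n_used[[g]]))
      e <- if (grp %in% names(est)) est[[grp]] else 0
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, group = grp, truth = f, estimate = e, se = se,
        within_3se = abs(e - f) <= 3 * se, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$gene, -out$truth), , drop = FALSE]
}

#' @export
print.closed_loop <- function(x, ...) {
  cat("closed_loop:", x$config$n_samples, "samples,",
      paste(x$config$genes, collapse = "+"), "\n")
  print(x$summary, row.names = FALSE)
  cat("\nrecovery (top groups):\n")
  print(head(x$recovery, 10L), row.names = FALSE, digits = 4)
  invisible(x)
}
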