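#' Type a simulated cohort
#'
#' Runs the full typing engine over a cohort: simulates each sample's read
#' pairs (identically to [synthesize_reads()], seed-for-seed), merges and
#' assigns them, calls per-amplicon variants and enumerates genotypes —
#' or, with `engine = "exact"`, types directly from the error-free
#' projected sequences (the pre-called-observation path).
#'
#' @param db an [allele_db()] covering the cohort's genes.
#' @param panel an [amplicon_panel()].
#' @param cohort a [sample_cohort()] result.
#' @param params a [typing_params()].
#' @param engine `"reads"` (simulate + call reads) or `"exact"`
#'   (noise-free observations straight from the allele projections).
#' @return data.frame, one row per sample x gene: `sample`, `gene`, `gl`,
#'   `n_candidates`, `flags` (semicolon-joined), and logical convenience
#'   columns `phase_ambiguous`, `novel`, `retest`, `exon23_only`.
#' @export
type_cohort <- function(db, panel, cohort, params = typing_params(),
                        engine = c("reads", "exact")) {
  engine <- match.arg(engine)
  index <- build_typing_index(db, panel, groups = cohort$groups)
  ei <- cohort_engine_inputs(db, panel, cohort, index)
  config <- cohort$config
  n <- config$n_samples
  out <- list()
  if (engine == "reads") {
    cls <- engine_classes(index, extra_sigs = ei$extra_sigs)
    eng <- cpp_type_cohort(cls$gene, cls$amp, cls$sigs, ei$haps[index$genes],
                           config$depth, config$read_len, config$error_rate,
                           params$min_minor_fraction, params$max_mismatch,
                           config$seed)
    for (gi in seq_along(index$genes)) {
      g <- index$genes[gi]
      ga <- which(cls$gene == gi)
      v1 <- lapply(ga, function(a) eng[[a]]$v1)
      v2 <- lapply(ga, function(a) eng[[a]]$v2)
      nr <- lapply(ga, function(a) eng[[a]]$nreads)
      dict <- lapply(ga, function(a) eng[[a]]$dict)
      low <- lapply(nr, function(x) x < params$min_depth)
      key <- do.call(paste, c(v1, v2, low, list(sep = ":")))
      uk <- unique(key)
      kidx <- match(key, uk)
      first <- match(seq_along(uk), kidx)
      calls <- lapply(first, function(i) {
        obs_list <- setNames(vector("list", length(index$amps)), index$amps)
        lowv <- logical(length(index$amps))
        for (j in seq_along(ga)) {
          ids <- c(v1[[j]][i], v2[[j]][i])
          obs_list[[j]] <- dict[[j]][ids[ids > 0L]]
          lowv[j] <- low[[j]][i]
        }
        names(lowv) <- index$amps
        type_from_obs_list(obs_list, lowv, g, index, NA_character_)
      })
      out[[g]] <- cohort_rows(calls, kidx, g, n)
    }
  } else {
    for (g in index$genes) {
      gidx <- index$gene_index[[g]]
      haps <- ei$haps[[g]]
      n_known <- length(gidx$alleles)
      cls1 <- ifelse(haps[, 1L] <= n_known, gidx$class_of_allele[pmin(haps[, 1L], n_known)], NA)
      cls2 <- ifelse(haps[, 2L] <= n_known, gidx$class_of_allele[pmin(haps[, 2L], n_known)], NA)
      key <- ifelse(is.na(cls1) | is.na(cls2), paste0("novel", seq_len(n)),
                    paste(pmin(cls1, cls2), pmax(cls1, cls2)))
      uk <- unique(key)
      kidx <- match(key, uk)
      first <- match(seq_along(uk), kidx)
      calls <- lapply(first, function(i) {
        obs_list <- lapply(setNames(index$amps, index$amps), function(a) {
          s1 <- hap_sig(i, 1L, a, haps, gidx, ei$extra_sigs[[g]], n_known)
          s2 <- hap_sig(i, 2L, a, haps, gidx, ei$extra_sigs[[g]], n_known)
          unique(c(s1, s2))
        })
        lowv <- setNames(rep(FALSE, length(index$amps)), index$amps)
        type_from_obs_list(obs_list, lowv, g, index, NA_character_)
      })
      out[[g]] <- cohort_rows(calls, kidx, g, n)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sample, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

hap_sig <- function(i, h, a, haps, gidx, extra, n_known) {
  idx <- haps[i, h]
  if (idx <= n_known) gidx$class_sig[gidx$class_of_allele[idx], a] else
    extra[[a]][idx - n_known]
}

cohort_rows <- function(calls, kidx, gene, n) {
  gl <- vapply(calls, `[[`, "", "gl")[kidx]
  ncand <- vapply(calls, function(c) length(c$pairs), 1L)[kidx]
  flags <- vapply(calls, function(c) paste(c$flags, collapse = ";"), "")[kidx]
  data.frame(sample = seq_len(n), gene = gene, gl = gl, n_candidates = ncand,
             flags = flags,
             phase_ambiguous = grepl("phase_ambiguous", flags),
             novel = grepl("novel_sequence|novel_combination", flags),
             retest = grepl("low_coverage_retest|novel_sequence|novel_combination", flags),
             exon23_only = grepl("exon23_only", flags),
             stringsAsFactors = FALSE)
}

#' Resolve phasing ambiguities across a cohort
#'
#' Applies [resolve_phasing()] to every phase-ambiguous result and records
#' the outcome: `gl_final` holds the retained genotype(s) and
#' `expected_error` the probability mass of the discarded alternatives.
#'
#' @param results a [type_cohort()] data.frame.
#' @param prior a [frequency_prior()].
#' @param odds_threshold see [resolve_phasing()].
#' @return `results` with added columns `gl_final`, `resolved`,
#'   `expected_error`.
#' @export
resolve_cohort <- function(results, prior, odds_threshold = 1000) {
  results$gl_final <- results$gl
  results$resolved <- FALSE
  results$expected_error <- 0
  amb <- which(results$phase_ambiguous & !is.na(results$gl))
  if (length(amb)) {
    key <- paste(results$gene[amb], results$gl[amb])
    for (k in unique(key)) {
      rows <- amb[key == k]
      r1 <- rows[1L]
      rc <- suppressWarnings(resolve_phasing(parse_gl(results$gl[r1]), prior,
                                             gene = results$gene[r1],
                                             odds_threshold = odds_threshold))
      results$gl_final[rows] <- rc$gl
      results$resolved[rows] <- rc$resolved
      results$expected_error[rows] <- rc$expected_error
    }
  }
  results
}

#' Summarize cohort typing outcomes
#' @param results a [type_cohort()] (optionally [resolve_cohort()]) frame.
#' @return data.frame per gene: numbers typed, phase-ambiguous, resolved,
#'   novel-flagged, retest-flagged.
#' @export
summarize_cohort <- function(results) {
  do.call(rbind, lapply(split(results, results$gene), function(r) {
    data.frame(gene = r$gene[1L],
               n = nrow(r),
               n_called = sum(!is.na(r$gl)),
               n_phase_ambiguous = sum(r$phase_ambiguous),
               n_resolved = if (!is.null(r$resolved)) sum(r$resolved) else NA_integer_,
               n_novel = sum(r$novel),
               n_retest = sum(r$retest),
               stringsAsFactors = FALSE)
  }))
}
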