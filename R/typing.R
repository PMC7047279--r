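#' Typing parameters
#'
#' Read-level thresholds for amplicon calling and gene assignment.
#'
#' @param min_depth minimum merged-read depth per amplicon; below it the
#'   amplicon is flagged for retest (default 50).
#' @param min_minor_fraction minimum minor-variant fraction for a second
#'   variant (and for a heterozygous column) to be accepted (default 0.25).
#' @param max_mismatch maximum mismatches tolerated when assigning a merged
#'   read to its nearest amplicon reference (default 5).
#' @param gene_margin minimum edit-distance margin between the best and
#'   second-best gene for unambiguous gene assignment (default 3).
#' @return A list of class `typing_params`.
#' @export
typing_params <- function(min_depth = 50L, min_minor_fraction = 0.25,
                          max_mismatch = 5L, gene_margin = 3L) {
  structure(list(min_depth = as.integer(min_depth),
                 min_minor_fraction = min_minor_fraction,
                 max_mismatch = as.integer(max_mismatch),
                 gene_margin = as.integer(gene_margin)),
            class = "typing_params")
}

#' Build a typing index
#'
#' Precomputes, per gene, the distinct signature classes (alleles identical
#' on every amplicon collapse into one class), their per-amplicon sequences
#' and their ambiguity-group display names. All genotype enumeration runs
#' against this index.
#'
#' @param db an [allele_db()].
#' @param panel an [amplicon_panel()].
#' @param groups optional precomputed [ambiguity_groups()] result.
#' @param representative_override passed to [ambiguity_groups()] when
#'   `groups` is `NULL`; defaults to the convention stored on the database
#'   ([db_representative_override()]).
#' @return A list of class `typing_index`.
#' @export
build_typing_index <- function(db, panel, groups = NULL,
                               representative_override = db_representative_override(db)) {
  if (is.null(groups)) {
    groups <- ambiguity_groups(db, panel,
                               representative_override = representative_override)
  }
  dm <- group_display_map(groups)
  sigs <- allele_signatures(db, panel, on_error = "drop")
  amps <- panel_amplicon_names(panel)
  genes <- db_genes(db)
  gidx <- list()
  for (g in genes) {
    s <- sigs[sigs$gene == g, , drop = FALSE]
    key <- sig_key(s, amps)
    cls <- match(key, unique(key))
    k <- max(cls)
    class_sig <- matrix("", nrow = k, ncol = length(amps),
                        dimnames = list(NULL, amps))
    class_display <- character(k)
    for (ci in seq_len(k)) {
      rows <- which(cls == ci)
      class_sig[ci, ] <- as.matrix(s[rows[1L], amps, drop = FALSE])
      disp <- unique(dm[s$first_field[rows]])
      if (length(disp) != 1L) stop("internal error: signature class spans ambiguity groups")
      class_display[ci] <- disp
    }
    gidx[[g]] <- list(alleles = s$allele, first_field = s$first_field,
                      display = unname(dm[s$first_field]),
                      class_of_allele = cls,
                      class_sig = class_sig, class_display = class_display)
  }
  structure(list(panel = panel, amps = amps, genes = genes,
                 groups = groups, display_map = dm, gene_index = gidx),
            class = "typing_index")
}

as_obs_list <- function(observations, amps) {
  if (is.data.frame(observations)) {
    need <- c("amplicon", "seq")
    if (!all(need %in% names(observations))) {
      stop("observation data.frame needs columns amplicon, seq")
    }
    obs <- split(observations$seq, factor(observations$amplicon, levels = amps))
  } else {
    obs <- observations
  }
  lapply(obs, unique)
}

enumerate_core <- function(obs, gidx, amps) {
  M <- gidx$class_sig
  have <- amps[vapply(obs[amps], function(x) length(x) > 0L, logical(1))]
  if (!length(have)) {
    return(list(pairs = list(), class_pairs = list(), flags = "low_coverage_retest"))
  }
  memb <- vapply(have, function(a) M[, a, drop = TRUE] %in% obs[[a]],
                 logical(nrow(M)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = nrow(M))
  cand <- which(rowSums(memb) == length(have))
  class_pairs <- list()
  if (length(cand)) {
    single <- vapply(have, function(a) length(obs[[a]]) == 1L, logical(1))
    for (ii in seq_along(cand)) {
      for (jj in ii:length(cand)) {
        i <- cand[ii]; j <- cand[jj]
        same <- M[i, have] == M[j, have]
        if (all(single == same)) {
          class_pairs[[length(class_pairs) + 1L]] <- c(i, j)
        }
      }
    }
  }
  disp_pairs <- lapply(class_pairs, function(p) {
    d <- gidx$class_display[p]
    d[allele_name_order(d)]
  })
  keys <- vapply(disp_pairs, paste, "", collapse = "+")
  keep <- !duplicated(keys)
  list(pairs = disp_pairs[keep], class_pairs = class_pairs, flags = character(0))
}

classify_novel_core <- function(obs, gidx, amps) {
  M <- gidx$class_sig
  unknown <- FALSE
  for (a in amps) {
    if (length(obs[[a]]) && any(!obs[[a]] %in% M[, a])) unknown <- TRUE
  }
  if (unknown) "novel_sequence" else "novel_combination"
}

make_call <- function(sample, gene, enum, obs, extra_flags = character(0)) {
  flags <- unique(c(enum$flags, extra_flags))
  pairs <- enum$pairs
  if (!length(pairs) && !"low_coverage_retest" %in% flags) {
    flags <- c(flags, attr(enum, "novel_flag"))
  }
  if (length(pairs) > 1L) flags <- c(flags, "phase_ambiguous")
  structure(list(sample = sample, gene = gene, pairs = pairs,
                 gl = if (length(pairs)) emit_gl(pairs) else NA_character_,
                 flags = unique(flags), observations = obs),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("genotype_call %s [%s]: %s%s\n",
              ifelse(is.na(x$sample), "", x$sample), x$gene,
              ifelse(is.na(x$gl), "<no call>", x$gl),
              if (length(x$flags)) paste0("  (", paste(x$flags, collapse = ", "), ")") else ""))
  invisible(x)
}

#' Enumerate genotypes consistent with unphased amplicon observations
#'
#' The core matching contract: a candidate genotype is an unordered pair of
#' alleles `(a, b)` such that for every amplicon the set of projected
#' sequences `{sig(a), sig(b)}` equals the observed variant set (a
#' single-variant observation requires both alleles to carry that
#' sequence). Candidates are reported at ambiguity-group resolution; more
#' than one surviving group pair means the observations are
#' phase-ambiguous. If no pair is consistent the call is flagged
#' `novel_sequence` (an observed sequence matches no known projection) or
#' `novel_combination` (all sequences known, but no allele pair carries the
#' combination).
#'
#' @param observations a named list amplicon -> character vector of observed
#'   sequences (1 or 2), or a data.frame with columns `amplicon`, `seq`.
#' @param db an [allele_db()] (ignored when `index` is given).
#' @param panel an [amplicon_panel()] (ignored when `index` is given).
#' @param gene gene to type against; inferred with [assign_gene()] if `NULL`.
#' @param index optional prebuilt [build_typing_index()].
#' @param sample optional sample id stored on the result.
#' @return A `genotype_call`: candidate group pairs, GL string and flags.
#' @examples
#' db <- allele_db(data.frame(
#'   gene = "MICA", allele = c("MICA*001", "MICA*002", "MICA*004"),
#'   exon2 = c("AAAA", "CCCC", "CCCC"), exon3 = c("GGGG", "TTTT", "GGGG")))
#' panel <- amplicon_panel(list(
#'   list(name = "ex2", segments = data.frame(exon = 2, start = 0)),
#'   list(name = "ex3", segments = data.frame(exon = 3, start = 0))))
#' enumerate_genotypes(list(ex2 = c("AAAA", "CCCC"), ex3 = c("GGGG", "TTTT")),
#'                     db, panel, gene = "MICA")
#' @export
enumerate_genotypes <- function(observations, db = NULL, panel = NULL,
                                gene = NULL, index = NULL, sample = NA_character_) {
  if (is.null(index)) index <- build_typing_index(db, panel)
  obs <- as_obs_list(observations, index$amps)
  if (is.null(gene)) {
    gene <- assign_gene(unlist(obs, use.names = FALSE), index = index)
  }
  gidx <- index$gene_index[[gene]]
  if (is.null(gidx)) stop("gene ", gene, " not in database")
  enum <- enumerate_core(obs, gidx, index$amps)
  attr(enum, "novel_flag") <- classify_novel_core(obs, gidx, index$amps)
  make_call(sample, gene, enum, obs)
}

#' Classify a no-call as novel sequence or novel combination
#'
#' @inheritParams enumerate_genotypes
#' @return `"novel_sequence"` or `"novel_combination"`.
#' @export
classify_novel <- function(observations, db = NULL, panel = NULL, gene = NULL,
                           index = NULL) {
  if (is.null(index)) index <- build_typing_index(db, panel)
  obs <- as_obs_list(observations, index$amps)
  if (is.null(gene)) gene <- assign_gene(unlist(obs, use.names = FALSE), index = index)
  classify_novel_core(obs, index$gene_index[[gene]], index$amps)
}

#' Fall back to exon 2/3-only typing
#'
#' When coverage fails only for the joined exon 4/5 amplicon, a result can
#' still be generated from exons 2 and 3 alone; the candidate set of this
#' sub-panel result is always a superset of (or equal to) the full-panel
#' result and the call is flagged `exon23_only`.
#'
#' @inheritParams enumerate_genotypes
#' @return A `genotype_call` flagged `exon23_only`.
#' @export
exon23_fallback <- function(observations, db = NULL, panel = NULL, gene = NULL,
                            index = NULL, sample = NA_character_) {
  if (is.null(index)) index <- build_typing_index(db, panel)
  sub_amps <- exon23_amps(index$panel)
  if (!length(sub_amps)) stop("panel has no exon-2/3-only amplicons")
  obs <- as_obs_list(observations, index$amps)
  obs_sub <- obs[sub_amps]
  if (is.null(gene)) gene <- assign_gene(unlist(obs_sub, use.names = FALSE), index = index)
  gidx <- index$gene_index[[gene]]
  enum <- enumerate_core(obs_sub, gidx, sub_amps)
  attr(enum, "novel_flag") <- classify_novel_core(obs_sub, gidx, sub_amps)
  make_call(sample, gene, enum, obs_sub, extra_flags = "exon23_only")
}

exon23_amps <- function(panel) {
  keep <- vapply(panel$amplicons, function(a) all(a$segments$exon %in% c(2L, 3L)),
                 logical(1))
  panel_amplicon_names(panel)[keep]
}

#' Assign observed sequences to a gene
#'
#' Picks the gene whose allele projections are nearest to the observed
#' sequences: an exact match wins outright; otherwise total edit distance is
#' used and the best gene must beat the runner-up by at least `gene_margin`.
#'
#' @param seqs character vector of observed amplicon sequences.
#' @param db,panel database and panel (ignored when `index` is given).
#' @param index optional [build_typing_index()].
#' @param gene_margin minimum distance margin (default 3).
#' @return Gene name. Throws an `ambiguous-gene` error on ties/small margins.
#' @export
assign_gene <- function(seqs, db = NULL, panel = NULL, index = NULL,
                        gene_margin = 3L) {
  if (is.null(index)) index <- build_typing_index(db, panel)
  stopifnot(length(seqs) >= 1L)
  genes <- index$genes
  if (length(genes) == 1L) return(genes)
  score <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    M <- index$gene_index[[g]]$class_sig
    score[g] <- sum(vapply(seqs, function(s) {
      if (any(M == s)) return(0)
      min(adist(s, as.vector(M)))
    }, numeric(1)))
  }
  o <- order(score)
  if (score[o[2L]] - score[o[1L]] < gene_margin) {
    stop(structure(class = c("micatype_ambiguous_gene", "error", "condition"),
                   list(message = sprintf(
                     "ambiguous gene assignment (%s: %g vs %s: %g)",
                     genes[o[1L]], score[o[1L]], genes[o[2L]], score[o[2L]]),
                     call = NULL)))
  }
  genes[o[1L]]
}

engine_classes <- function(index, extra_sigs = NULL) {
  class_gene <- integer(0)
  class_amp <- integer(0)
  class_name <- character(0)
  class_sigs <- list()
  for (gi in seq_along(index$genes)) {
    g <- index$genes[gi]
    gidx <- index$gene_index[[g]]
    for (ai in seq_along(index$amps)) {
      sigs <- gidx$class_sig[gidx$class_of_allele, index$amps[ai]]
      if (!is.null(extra_sigs[[g]])) sigs <- c(sigs, extra_sigs[[g]][[index$amps[ai]]])
      class_gene <- c(class_gene, gi)
      class_amp <- c(class_amp, ai)
      class_name <- c(class_name, paste0(g, ":", index$amps[ai]))
      class_sigs[[length(class_sigs) + 1L]] <- unname(sigs)
    }
  }
  list(gene = class_gene, amp = class_amp, name = class_name, sigs = class_sigs)
}

#' Call per-amplicon sequence variants from one sample's read pairs
#'
#' Merges each read pair by overlap consensus, assigns the merged read to
#' the nearest gene/amplicon reference, and calls at most two sequence
#' variants per amplicon by positional consensus: heterozygous columns are
#' those whose minor-base fraction reaches `min_minor_fraction`, and the
#' per-read base patterns across those columns define (and count) the two
#' variants. Amplicons below `min_depth` merged reads are flagged for
#' retest.
#'
#' @param r1,r2 character vectors: the sample's paired reads (R2 as
#'   sequenced, i.e. reverse-complement of the amplicon 3' end).
#' @param db,panel database and panel (ignored when `index` is given).
#' @param index optional [build_typing_index()].
#' @param params a [typing_params()].
#' @return data.frame: `gene`, `amplicon`, `seq`, `count`, `depth`,
#'   `low_coverage` per called variant (amplicons with zero assigned reads
#'   appear with `NA` sequence).
#' @export
call_amplicons <- function(r1, r2, db = NULL, panel = NULL, index = NULL,
                           params = typing_params()) {
  if (is.null(index)) index <- build_typing_index(db, panel)
  cls <- engine_classes(index)
  res <- cpp_call_sample(as.character(r1), as.character(r2), cls$sigs,
                         params$min_minor_fraction, params$max_mismatch)
  rows <- list()
  for (a in seq_along(res)) {
    r <- res[[a]]
    g <- index$genes[cls$gene[a]]
    amp <- index$amps[cls$amp[a]]
    low <- r$nreads < params$min_depth
    if (!length(r$variants)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, amplicon = amp, seq = NA_character_, count = 0L,
        depth = r$nreads, low_coverage = TRUE, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, amplicon = amp, seq = r$variants, count = r$counts,
        depth = r$nreads, low_coverage = low, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Type one sample from reads or pre-called observations
#'
#' @param r1,r2 the sample's paired reads (alternatively supply `obs`).
#' @param obs pre-called observations: data.frame with columns `gene`
#'   (optional), `amplicon`, `seq` (one row per variant).
#' @param db,panel,index,params as in [call_amplicons()].
#' @param sample sample id.
#' @return Named list of `genotype_call` objects, one per gene with data.
#' @export
type_sample <- function(r1 = NULL, r2 = NULL, obs = NULL, db = NULL,
                        panel = NULL, index = NULL, params = typing_params(),
                        sample = NA_character_) {
  if (is.null(index)) index <- build_typing_index(db, panel)
  if (is.null(obs)) {
    if (is.null(r1) || is.null(r2)) stop("supply reads (r1, r2) or observations (obs)")
    obs <- call_amplicons(r1, r2, index = index, params = params)
    obs <- obs[!is.na(obs$seq) | obs$depth > 0, , drop = FALSE]
  } else {
    if (is.null(obs$depth)) obs$depth <- params$min_depth
    if (is.null(obs$low_coverage)) obs$low_coverage <- FALSE
    if (is.null(obs$gene)) {
      obs$gene <- vapply(seq_len(nrow(obs)), function(i)
        assign_gene(obs$seq[i], index = index, gene_margin = params$gene_margin),
        character(1))
    }
  }
  out <- list()
  for (g in unique(obs$gene[!is.na(obs$seq)])) {
    og <- obs[obs$gene == g, , drop = FALSE]
    obs_list <- lapply(setNames(index$amps, index$amps), function(a)
      og$seq[og$amplicon == a & !is.na(og$seq) & !og$low_coverage])
    low <- vapply(setNames(index$amps, index$amps), function(a) {
      rows <- og$amplicon == a
      any(rows & og$low_coverage) || !any(rows)
    }, logical(1))
    out[[g]] <- type_from_obs_list(obs_list, low, g, index, sample)
  }
  out
}

type_from_obs_list <- function(obs_list, low, gene, index, sample) {
  sub_amps <- exon23_amps(index$panel)
  gidx <- index$gene_index[[gene]]
  low_amps <- index$amps[low]
  if (length(low_amps)) {
    if (all(!low[sub_amps]) && length(sub_amps)) {
      call <- exon23_fallback(obs_list, index = index, gene = gene, sample = sample)
      call$flags <- unique(c(call$flags, "low_coverage_retest"))
      return(call)
    }
    enum <- list(pairs = list(), flags = "low_coverage_retest")
    return(make_call(sample, gene, enum, obs_list))
  }
  enum <- enumerate_core(obs_list, gidx, index$amps)
  attr(enum, "novel_flag") <- classify_novel_core(obs_list, gidx, index$amps)
  make_call(sample, gene, enum, obs_list)
}
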