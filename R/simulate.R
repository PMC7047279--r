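DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

rotate_base <- function(b, shift = 1L) {
  DNA_BASES[(match(b, DNA_BASES) - 1L + shift) %% 4L + 1L]
}

mutate_seq <- function(seq, pos, shift = 1L) {
  substr(seq, pos, pos) <- rotate_base(substr(seq, pos, pos), shift)
  seq
}

default_exon_lengths <- function() {
  c(exon1 = 87L, exon2 = 255L, exon3 = 288L, exon4 = 280L, exon5 = 108L,
    exon6 = 90L)
}

#' German reference allele-group frequencies
#'
#' First-field allele-group frequencies for donors of German descent, as
#' determined in a registry cohort of about 1.2 million samples: the top
#' MICA groups are MICA*008 (42.3%), MICA*002 (11.7%), MICA*009# (8.8%),
#' MICA*010# (7.7%) and MICA*004 (6.5%); the top MICB groups are MICB*005#
#' (43.9%), MICB*004# (21.7%), MICB*002 (18.9%), MICB*008 (11.0%),
#' MICB*014# (2.2%) and MICB*013 (1.4%). Groups marked `source = "modeled"`
#' fill the remainder of the distribution (the registry survey reports only
#' the groups above; the tail is modeled with plausible European values so
#' the listed MICA groups reach the reported cumulative 99.5%, and so that
#' the MICB*018/MICB*019 product matches the reported heterozygote
#' likelihood of 1.9e-8). These values are the default simulation truth.
#'
#' @param gene `"MICA"` or `"MICB"`.
#' @return data.frame with columns `group`, `percent`, `source`.
#' @examples
#' german_allele_frequencies("MICB")
#' @export
german_allele_frequencies <- function(gene = c("MICA", "MICB")) {
  gene <- match.arg(gene)
  if (gene == "MICA") {
    data.frame(
      group = c("MICA*008", "MICA*002", "MICA*009#", "MICA*010#", "MICA*004",
                "MICA*007", "MICA*001", "MICA*017", "MICA*012", "MICA*011",
                "MICA*016", "MICA*019", "MICA*018", "MICA*027#", "MICA*015"),
      percent = c(42.3, 11.7, 8.8, 7.7, 6.5,
                  4.9, 4.2, 3.1, 2.6, 2.0,
                  1.8, 1.3, 1.1, 0.9, 0.6),
      source = c(rep("registry", 5L), rep("modeled", 10L)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      group = c("MICB*005#", "MICB*004#", "MICB*002", "MICB*008", "MICB*014#",
                "MICB*013", "MICB*018", "MICB*019"),
      percent = c(43.9, 21.7, 18.9, 11.0, 2.2, 1.4, 0.019, 0.005),
      source = c(rep("registry", 6L), "modeled", "modeled"),
      stringsAsFactors = FALSE)
  }
}

#' Renormalize a frequency table to proportions summing to one
#' @param x named numeric vector (e.g. percentages) or a data.frame from
#'   [german_allele_frequencies()].
#' @return Named numeric vector of proportions summing to 1.
#' @export
renormalize_frequencies <- function(x) {
  if (is.data.frame(x)) x <- setNames(x$percent, x$group)
  x / sum(x)
}

new_seq_pool <- function(lengths) {
  env <- new.env(parent = emptyenv())
  env$pools <- list()
  env
}

pool_draw <- function(pool, key, range_lo, range_hi) {
  if (is.null(pool$pools[[key]])) {
    pool$pools[[key]] <- sample(seq.int(range_lo, range_hi))
  }
  v <- pool$pools[[key]]
  if (!length(v)) stop("position pool exhausted for ", key)
  pool$pools[[key]] <- v[-1L]
  v[1L]
}

# Builder used by both the random and the named (German-style) synthetic
# databases: starts every allele from the gene's base exons and applies
# substitution recipes. Distinct covered positions per allele guarantee
# distinct signatures except where sharing is engineered.
synth_gene_builder <- function(gene, exon_lengths) {
  base <- lapply(exon_lengths, random_dna)
  names(base) <- names(exon_lengths)
  pool <- new_seq_pool(exon_lengths)
  alleles <- list()
  add <- function(name, recipe = list(), copy_of = NULL) {
    exons <- if (is.null(copy_of)) base else alleles[[copy_of]]$exons
    for (r in recipe) {
      col <- paste0("exon", r$exon)
      exons[[col]] <- mutate_seq(exons[[col]], r$pos,
                                 if (is.null(r$shift)) 1L else r$shift)
    }
    alleles[[name]] <<- list(name = name, exons = exons)
    invisible(name)
  }
  draw <- function(exon, covered = TRUE) {
    L <- exon_lengths[[paste0("exon", exon)]]
    if (exon == 4L) {
      if (covered) pool_draw(pool, "exon4cov", 66L, L) else pool_draw(pool, "exon4unc", 1L, 65L)
    } else if (exon == 5L) {
      if (covered) pool_draw(pool, "exon5cov", 1L, L - 13L) else pool_draw(pool, "exon5unc", L - 12L, L)
    } else {
      pool_draw(pool, paste0("exon", exon), 1L, L)
    }
  }
  unique_triple <- function() {
    list(list(exon = 2L, pos = draw(2L)),
         list(exon = 3L, pos = draw(3L)),
         list(exon = 4L, pos = draw(4L)))
  }
  as_db_rows <- function() {
    do.call(rbind, lapply(alleles, function(a) {
      row <- data.frame(gene = gene, allele = a$name, stringsAsFactors = FALSE)
      for (k in 1:6) row[[paste0("exon", k)]] <- a$exons[[paste0("exon", k)]]
      row
    }))
  }
  list(add = add, draw = draw, unique_triple = unique_triple,
       rows = as_db_rows, base = base)
}

#' Generate a synthetic allele database
#'
#' Builds a random exon-level allele database with controlled ambiguity
#' structure for testing: all alleles of a gene share random base exon
#' sequences and differ by engineered substitutions at distinct covered
#' positions, so signatures are pairwise distinct except where a fixture
#' makes them collide.
#'
#' Fixtures:
#' \describe{
#'   \item{`exon6_twin`}{adds one allele identical to another in all covered
#'     regions but differing in exon 6 — exactly one two-member ambiguity
#'     group.}
#'   \item{`phase_quartet`}{makes the first four alleles `P1..P4` of each
#'     gene satisfy `sig(P1) U sig(P2) = sig(P3) U sig(P4)` per amplicon, so
#'     the heterozygote P1+P2 is phase-ambiguous with P3+P4.}
#' }
#'
#' @param seed integer seed; the database is deterministic given the seed.
#' @param n_alleles named integer vector: alleles per gene (>= 4 when the
#'   quartet fixture is requested, >= 5 for both fixtures).
#' @param fixtures list with logical entries `exon6_twin`, `phase_quartet`.
#' @param exon_lengths named integer vector `exon1`..`exon6`.
#' @return An [allele_db()].
#' @export
make_synthetic_db <- function(seed = 1L,
                              n_alleles = c(MICA = 10L, MICB = 10L),
                              fixtures = list(exon6_twin = TRUE,
                                              phase_quartet = TRUE),
                              exon_lengths = default_exon_lengths()) {
  fx <- list(exon6_twin = isTRUE(fixtures$exon6_twin),
             phase_quartet = isTRUE(fixtures$phase_quartet))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  for (g in names(n_alleles)) {
    n <- n_alleles[[g]]
    if (fx$phase_quartet && n < 4L) stop("phase_quartet requires >= 4 alleles per gene")
    b <- synth_gene_builder(g, exon_lengths)
    nm <- function(i) sprintf("%s*%03d", g, i)
    start <- 1L
    if (fx$phase_quartet) {
      pa <- b$draw(2L); qa <- b$draw(2L)
      pb <- b$draw(3L); qb <- b$draw(3L)
      b$add(nm(1L), list(list(exon = 2L, pos = pa), list(exon = 3L, pos = pb)))
      b$add(nm(2L), list(list(exon = 2L, pos = qa), list(exon = 3L, pos = qb)))
      b$add(nm(3L), list(list(exon = 2L, pos = pa), list(exon = 3L, pos = qb)))
      b$add(nm(4L), list(list(exon = 2L, pos = qa), list(exon = 3L, pos = pb)))
      start <- 5L
    }
    for (i in seq.int(start, n)) b$add(nm(i), b$unique_triple())
    if (fx$exon6_twin) {
      target <- if (n >= 5L || !fx$phase_quartet) nm(n) else nm(4L)
      b$add(nm(n + 1L), list(list(exon = 6L, pos = b$draw(6L))), copy_of = target)
    }
    rows[[g]] <- b$rows()
  }
  allele_db(do.call(rbind, rows), release = sprintf("synthetic-seed%d", seed))
}

#' The packaged synthetic German reference database
#'
#' A deterministic synthetic exon-level database whose ambiguity structure
#' under the default panel reproduces the reporting conventions of the
#' German registry survey: the hash groups MICA*009# (MICA*009, MICA*049),
#' MICA*010# (MICA*010, MICA*065, MICA*069), MICA*027# (MICA*027,
#' MICA*048), MICB*004# (MICB*004, MICB*028), MICB*005# (MICB*003,
#' MICB*005, MICB*006, MICB*010) and MICB*014# (MICB*014, MICB*015), the
#' unambiguous second-field variant MICA*009:02, and the dominant MICB
#' phasing quartet in which the heterozygote MICB*002 + MICB*005:02 cannot
#' be phased apart from MICB*018 + MICB*019. Sequences are synthetic; only
#' the ambiguity structure (which alleles collide, and where: exon 6, the
#' uncovered first 65 bases of exon 4, the uncovered last 13 bases of exon
#' 5) mirrors the real panel.
#'
#' The attribute `representative_override` carries the reporting convention
#' that the MICB*003/005/006/010 group is displayed as `MICB*005#`.
#'
#' @param genes which genes to include.
#' @param seed integer seed (fixed default: this is a reference object).
#' @return An [allele_db()] with attribute `representative_override`.
#' @export
make_german_reference_db <- function(genes = c("MICA", "MICB"), seed = 20L) {
  genes <- match.arg(genes, c("MICA", "MICB"), several.ok = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  exon_lengths <- default_exon_lengths()
  rows <- list()
  if ("MICA" %in% genes) {
    b <- synth_gene_builder("MICA", exon_lengths)
    primaries <- c("MICA*008:01", "MICA*002:01", "MICA*009:01", "MICA*010",
                   "MICA*004", "MICA*007", "MICA*001", "MICA*017", "MICA*012",
                   "MICA*011", "MICA*016", "MICA*019", "MICA*018", "MICA*027",
                   "MICA*015")
    for (p in primaries) b$add(p, b$unique_triple())
    # uncovered-region twins behind the Table-1-style hash groups
    b$add("MICA*049", list(list(exon = 6L, pos = b$draw(6L))), copy_of = "MICA*009:01")
    b$add("MICA*009:02", list(list(exon = 3L, pos = b$draw(3L))), copy_of = "MICA*009:01")
    b$add("MICA*069", list(list(exon = 6L, pos = b$draw(6L))), copy_of = "MICA*010")
    b$add("MICA*065", list(list(exon = 4L, pos = b$draw(4L, covered = FALSE))),
          copy_of = "MICA*010")
    b$add("MICA*048", list(list(exon = 6L, pos = b$draw(6L))), copy_of = "MICA*027")
    rows[["MICA"]] <- b$rows()
  }
  if ("MICB" %in% genes) {
    b <- synth_gene_builder("MICB", exon_lengths)
    # phasing quartet: MICB*002 + MICB*005:02 is unphaseable from
    # MICB*018 + MICB*019 (shared exon-2/exon-3 variant pattern)
    pa <- b$draw(2L); qa <- b$draw(2L)
    pb <- b$draw(3L); qb <- b$draw(3L)
    b$add("MICB*002", list(list(exon = 2L, pos = pa), list(exon = 3L, pos = pb)))
    b$add("MICB*005:02", list(list(exon = 2L, pos = qa), list(exon = 3L, pos = qb)))
    b$add("MICB*018", list(list(exon = 2L, pos = pa), list(exon = 3L, pos = qb)))
    b$add("MICB*019", list(list(exon = 2L, pos = qa), list(exon = 3L, pos = pb)))
    for (p in c("MICB*004", "MICB*008", "MICB*013", "MICB*014")) {
      b$add(p, b$unique_triple())
    }
    # MICB*005# hash group: covered regions identical to MICB*005:02
    b$add("MICB*003", list(list(exon = 4L, pos = b$draw(4L, covered = FALSE)),
                           list(exon = 6L, pos = b$draw(6L))),
          copy_of = "MICB*005:02")
    b$add("MICB*006", list(list(exon = 6L, pos = b$draw(6L))), copy_of = "MICB*005:02")
    b$add("MICB*010", list(list(exon = 6L, pos = b$draw(6L), shift = 2L)),
          copy_of = "MICB*005:02")
    b$add("MICB*028", list(list(exon = 6L, pos = b$draw(6L))), copy_of = "MICB*004")
    b$add("MICB*015", list(list(exon = 6L, pos = b$draw(6L))), copy_of = "MICB*014")
    rows[["MICB"]] <- b$rows()
  }
  db <- allele_db(do.call(rbind, rows), release = "synthetic-german-reference")
  attr(db, "representative_override") <- c("MICB*003" = "MICB*005")
  db
}

#' Representative-override convention stored on a database
#' @param db an [allele_db()].
#' @return Named character vector or `NULL`.
#' @export
db_representative_override <- function(db) attr(db, "representative_override")

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulation configuration
#'
#' Study conditions for cohort simulation. Defaults model the production
#' assay: 1000 read pairs per amplicon, 2 x 249 bp paired-end reads, 1%
#' substitution error, and a 0.5% per-sample chance of carrying one novel
#' allele.
#'
#' @param seed integer seed driving genotype draws, novel injection and
#'   read simulation.
#' @param n_samples cohort size.
#' @param genes genes to simulate.
#' @param frequencies named list gene -> named numeric of group
#'   frequencies (any scale; renormalized to 1). Default: the German
#'   reference frequencies.
#' @param depth read pairs per amplicon per sample.
#' @param read_len read length (bp).
#' @param error_rate per-base substitution error rate.
#' @param novel_rate per-sample probability of carrying one novel allele
#'   (mutated copy, 1-3 substitutions in covered regions, of a drawn
#'   allele).
#' @param novel_uncovered if `TRUE`, novel substitutions are placed in
#'   uncovered regions instead (the undetectable false-negative case).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_samples = 1000L,
                              genes = c("MICA", "MICB"), frequencies = NULL,
                              depth = 1000L, read_len = 249L,
                              error_rate = 0.01, novel_rate = 0.005,
                              novel_uncovered = FALSE) {
  if (is.null(frequencies)) {
    frequencies <- lapply(setNames(genes, genes), function(g)
      renormalize_frequencies(german_allele_frequencies(g)))
  }
  stopifnot(error_rate >= 0, error_rate <= 1, novel_rate >= 0, novel_rate <= 1)
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 genes = genes, frequencies = frequencies,
                 depth = as.integer(depth), read_len = as.integer(read_len),
                 error_rate = error_rate, novel_rate = novel_rate,
                 novel_uncovered = novel_uncovered),
            class = "simulation_config")
}

covered_positions <- function(allele, panel) {
  al <- as.list(allele)
  out <- list()
  for (a in panel$amplicons) {
    seg <- a$segments
    for (i in seq_len(nrow(seg))) {
      seq <- al[[paste0("exon", seg$exon[i])]]
      L <- nchar(seq)
      s <- seg$start[i]
      e <- (if (is.na(seg$end[i])) L else seg$end[i]) - seg$trim_end[i]
      out[[length(out) + 1L]] <- data.frame(exon = seg$exon[i], pos = (s + 1L):e)
    }
  }
  do.call(rbind, out)
}

uncovered_positions <- function(allele, panel) {
  al <- as.list(allele)
  cov <- covered_positions(allele, panel)
  out <- list()
  for (k in 1:6) {
    seq <- al[[paste0("exon", k)]]
    if (is.null(seq) || is.na(seq)) next
    pos <- setdiff(seq_len(nchar(seq)), cov$pos[cov$exon == k])
    if (length(pos)) out[[length(out) + 1L]] <- data.frame(exon = k, pos = pos)
  }
  do.call(rbind, out)
}

#' Draw a diploid cohort under Hardy-Weinberg equilibrium
#'
#' Each sample draws two alleles per gene i.i.d. from the configured
#' group-frequency table (a drawn group contributes a uniformly chosen
#' member allele). With probability `novel_rate` a sample carries a novel
#' allele: one haplotype of one gene is replaced by a mutated copy (1-3
#' substitutions in panel-covered regions, or uncovered regions when
#' `novel_uncovered`).
#'
#' @param db an [allele_db()] (typically [make_german_reference_db()] or
#'   [make_synthetic_db()]).
#' @param config a [simulation_config()].
#' @param panel an [amplicon_panel()].
#' @return An object of class `mic_cohort`: list with `truth` (data.frame:
#'   `sample`, `gene`, `allele1`, `allele2`, `group1`, `group2`, `novel`,
#'   `novel_hap`), `novel_alleles` (data.frame of mutated allele rows with
#'   `sample`, `gene`, `hap`, `base_allele` and exon columns), `config`,
#'   and `groups` (the [ambiguity_groups()] used for group truth).
#' @export
sample_cohort <- function(db, config = simulation_config(),
                          panel = default_panel()) {
  genes <- intersect(config$genes, db_genes(db))
  if (!length(genes)) stop("config genes not present in database")
  groups <- ambiguity_groups(db, panel,
                             representative_override = db_representative_override(db))
  dm <- group_display_map(groups)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_samples
  truth <- list()
  for (g in genes) {
    f <- renormalize_frequencies(config$frequencies[[g]])
    if (!all(names(f) %in% groups$display[groups$gene == g])) {
      stop("frequency table names not all present as group displays for ", g, ": ",
           paste(setdiff(names(f), groups$display), collapse = ", "))
    }
    members <- lapply(setNames(names(f), names(f)), function(d) {
      ffs <- strsplit(groups$members[groups$display == d], ",", fixed = TRUE)[[1L]]
      db$allele[db$gene == g & db$first_field %in% ffs]
    })
    gdraw <- sample(names(f), 2L * n, replace = TRUE, prob = f)
    adraw <- vapply(gdraw, function(d) {
      m <- members[[d]]
      if (length(m) == 1L) m else m[sample.int(length(m), 1L)]
    }, character(1), USE.NAMES = FALSE)
    truth[[g]] <- data.frame(
      sample = seq_len(n), gene = g,
      allele1 = adraw[seq_len(n)], allele2 = adraw[n + seq_len(n)],
      group1 = gdraw[seq_len(n)], group2 = gdraw[n + seq_len(n)],
      novel = FALSE, novel_hap = NA_integer_, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  novel_rows <- list()
  if (config$novel_rate > 0) {
    hit <- which(runif(n) < config$novel_rate)
    for (s in hit) {
      g <- if (length(genes) == 1L) genes else genes[sample.int(length(genes), 1L)]
      hap <- sample.int(2L, 1L)
      ti <- which(truth$sample == s & truth$gene == g)
      base_name <- truth[[paste0("allele", hap)]][ti]
      row <- db[db$allele == base_name, , drop = FALSE]
      k <- sample.int(3L, 1L)
      pos_tab <- if (config$novel_uncovered) uncovered_positions(row, panel) else
        covered_positions(row, panel)
      picks <- pos_tab[sample.int(nrow(pos_tab), k), , drop = FALSE]
      exons <- as.list(row)[EXON_COLS]
      for (j in seq_len(nrow(picks))) {
        col <- paste0("exon", picks$exon[j])
        exons[[col]] <- mutate_seq(exons[[col]], picks$pos[j],
                                   shift = sample.int(3L, 1L))
      }
      nr <- data.frame(sample = s, gene = g, hap = hap, base_allele = base_name,
                       name = sprintf("novel:%d:%s", s, g), stringsAsFactors = FALSE)
      for (col in EXON_COLS) nr[[col]] <- exons[[col]]
      novel_rows[[length(novel_rows) + 1L]] <- nr
      truth$novel[ti] <- TRUE
      truth$novel_hap[ti] <- hap
    }
  }
  novel_alleles <- if (length(novel_rows)) do.call(rbind, novel_rows) else
    data.frame(sample = integer(0), gene = character(0), hap = integer(0),
               base_allele = character(0), name = character(0))
  structure(list(truth = truth, novel_alleles = novel_alleles,
                 config = config, groups = groups, genes = genes),
            class = "mic_cohort")
}

#' @export
print.mic_cohort <- function(x, ...) {
  cat(sprintf("mic_cohort: %d samples, genes %s, %d novel-injected\n",
              x$config$n_samples, paste(x$genes, collapse = "+"),
              length(unique(x$novel_alleles$sample))))
  invisible(x)
}

# Haplotype signature lookup for a cohort: per gene, the per-allele
# projected sequence of each amplicon (database alleles first, then the
# cohort's novel alleles) and the per-sample haplotype indices into it.
cohort_engine_inputs <- function(db, panel, cohort, index) {
  genes <- cohort$genes
  if (!identical(sort(genes), sort(index$genes))) {
    stop("cohort genes must match database genes (subset the database first)")
  }
  extra_sigs <- list()
  haps <- list()
  for (g in index$genes) {
    gidx <- index$gene_index[[g]]
    nov <- cohort$novel_alleles[cohort$novel_alleles$gene == g, , drop = FALSE]
    extra <- NULL
    if (nrow(nov)) {
      sig_list <- lapply(seq_len(nrow(nov)), function(i) project_allele(nov[i, ], panel))
      extra <- lapply(setNames(index$amps, index$amps), function(a)
        vapply(sig_list, `[[`, "", a))
    }
    extra_sigs[[g]] <- extra
    tg <- cohort$truth[cohort$truth$gene == g, , drop = FALSE]
    tg <- tg[order(tg$sample), , drop = FALSE]
    h <- cbind(match(tg$allele1, gidx$alleles), match(tg$allele2, gidx$alleles))
    if (nrow(nov)) {
      for (i in seq_len(nrow(nov))) {
        h[nov$sample[i], nov$hap[i]] <- length(gidx$alleles) + i
      }
    }
    storage.mode(h) <- "integer"
    haps[[g]] <- h
  }
  list(extra_sigs = extra_sigs, haps = haps)
}

#' Synthesize paired-end amplicon reads for a cohort
#'
#' For every sample, gene, amplicon and haplotype, `depth/2` read pairs are
#' generated covering the amplicon from both ends (R1 from the 5' end, R2
#' reverse-complement from the 3' end) with i.i.d. substitution errors at
#' the configured rate. Deterministic given the config seed.
#'
#' @param cohort a [sample_cohort()] result.
#' @param db,panel database and panel used to draw the cohort.
#' @param dir output directory for `reads_R1.fastq` / `reads_R2.fastq`;
#'   `NULL` returns the reads in memory instead.
#' @return Invisibly, a list with `r1`, `r2` (character vectors), `name`
#'   (read ids `S<sample>:<n>`) and `files` (paths or `NULL`).
#' @export
synthesize_reads <- function(cohort, db, panel = default_panel(), dir = NULL) {
  config <- cohort$config
  index <- build_typing_index(db, panel, groups = cohort$groups)
  amp_len_max <- 2L * config$read_len
  ei <- cohort_engine_inputs(db, panel, cohort, index)
  r1 <- list(); r2 <- list(); nm <- list()
  for (i in seq_len(config$n_samples)) {
    cnt <- 0L
    for (gi in seq_along(index$genes)) {
      g <- index$genes[gi]
      gidx <- index$gene_index[[g]]
      for (ai in seq_along(index$amps)) {
        a <- index$amps[ai]
        all_sigs <- c(gidx$class_sig[gidx$class_of_allele, a],
                      ei$extra_sigs[[g]][[a]])
        for (h in 1:2) {
          seq <- all_sigs[ei$haps[[g]][i, h]]
          if (nchar(seq) > amp_len_max) {
            stop(sprintf("amplicon %s (%d bp) exceeds 2 x read length (%d bp)",
                         a, nchar(seq), amp_len_max))
          }
          pr <- cpp_sim_pairs(seq, max(1L, config$depth %/% 2L), config$read_len,
                              config$error_rate, config$seed, i, gi, ai, h)
          r1[[length(r1) + 1L]] <- pr$r1
          r2[[length(r2) + 1L]] <- pr$r2
          nm[[length(nm) + 1L]] <- sprintf("S%d:%d", i, cnt + seq_along(pr$r1))
          cnt <- cnt + length(pr$r1)
        }
      }
    }
  }
  r1 <- unlist(r1); r2 <- unlist(r2); nm <- unlist(nm)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- file.path(dir, c("reads_R1.fastq", "reads_R2.fastq"))
    write_fastq(nm, r1, files[1L])
    write_fastq(nm, r2, files[2L])
  }
  invisible(list(r1 = r1, r2 = r2, name = nm, files = files))
}

write_fastq <- function(names, seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names, "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), con)
  invisible(path)
}

#' Read paired FASTQ files produced by [synthesize_reads()]
#'
#' @param r1_path,r2_path FASTQ files (read ids must match pairwise).
#' @return data.frame with columns `name`, `sample` (parsed from the
#'   `S<sample>:` id prefix, `NA` if absent), `r1`, `r2`.
#' @export
read_paired_fastq <- function(r1_path, r2_path) {
  f1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  f2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(f1) != length(f2) || !identical(names(f1), names(f2))) {
    stop("R1/R2 read ids do not match")
  }
  nm <- names(f1)
  sample <- suppressWarnings(as.integer(sub("^S([0-9]+):.*$", "\\1", nm)))
  data.frame(name = nm, sample = sample, r1 = as.character(f1),
             r2 = as.character(f2), stringsAsFactors = FALSE)
}

#' Write / read the cohort truth table
#' @param cohort a [sample_cohort()] result.
#' @param path TSV file.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_truth <- function(cohort, path) {
  write.table(cohort$truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) read.delim(path, stringsAsFactors = FALSE)
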