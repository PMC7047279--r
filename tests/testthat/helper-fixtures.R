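# Small deterministic fixtures and brute-force oracles shared across tests.

two_amp_panel <- function() {
  amplicon_panel(list(
    list(name = "ex2", segments = data.frame(exon = 2L, start = 0L)),
    list(name = "ex3", segments = data.frame(exon = 3L, start = 0L))
  ), name = "toy2")
}

# Four alleles over two amplicons with signatures A=(x1,y1), B=(x2,y2),
# C=(x2,y1), D=(x1,y2): the canonical phase-ambiguity quartet.
quartet_db <- function(include_d = TRUE) {
  x1 <- "ACGTACGTACGTACGTACGT"; x2 <- "ACGTACGTACGTACGTACGA"
  y1 <- "GGGGCCCCAAAATTTTGGGG"; y2 <- "GGGGCCCCAAAATTTTGGGC"
  tab <- data.frame(
    gene = "MICA",
    allele = c("MICA*001", "MICA*002", "MICA*003", "MICA*004"),
    exon2 = c(x1, x2, x2, x1),
    exon3 = c(y1, y2, y1, y2),
    stringsAsFactors = FALSE)
  if (!include_d) tab <- tab[1:3, ]
  allele_db(tab)
}

quartet_seqs <- function() {
  list(x1 = "ACGTACGTACGTACGTACGT", x2 = "ACGTACGTACGTACGTACGA",
       y1 = "GGGGCCCCAAAATTTTGGGG", y2 = "GGGGCCCCAAAATTTTGGGC")
}

# A random exon-level database; with prob `twin_prob` an allele duplicates
# another allele's covered exons (so ambiguity groups arise by chance).
random_test_db <- function(seed, n = 8L, gene = "MICA", twin_prob = 0.3,
                           len2 = 12L, len3 = 12L) {
  set.seed(seed)
  rand <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  exon2 <- character(n); exon3 <- character(n); exon6 <- character(n)
  for (i in seq_len(n)) {
    if (i > 1L && runif(1) < twin_prob) {
      j <- sample.int(i - 1L, 1L)
      exon2[i] <- exon2[j]; exon3[i] <- exon3[j]
    } else {
      exon2[i] <- rand(len2); exon3[i] <- rand(len3)
    }
    exon6[i] <- rand(8L)
  }
  allele_db(data.frame(gene = gene, allele = sprintf("%s*%03d", gene, seq_len(n)),
                       exon2 = exon2, exon3 = exon3, exon6 = exon6,
                       stringsAsFactors = FALSE))
}

# ---- independent oracles (naive O(n^2) scans, no shared code paths) ----

oracle_signatures <- function(db, panel) {
  lapply(seq_len(nrow(db)), function(i) project_allele(db[i, ], panel))
}

# Partition of first-field groups by transitive closure over identical
# signatures, computed by repeated pairwise merging of member sets.
oracle_ambiguity_partition <- function(db, panel) {
  sigs <- oracle_signatures(db, panel)
  out <- list()
  for (g in unique(db$gene)) {
    idx <- which(db$gene == g)
    sets <- lapply(unique(db$first_field[idx]), function(ff) ff)
    names(sets) <- unique(db$first_field[idx])
    sets <- lapply(sets, identity)
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (i in idx) for (j in idx) {
        if (i < j && identical(sigs[[i]], sigs[[j]])) {
          si <- which(vapply(sets, function(s) db$first_field[i] %in% s, logical(1)))
          sj <- which(vapply(sets, function(s) db$first_field[j] %in% s, logical(1)))
          if (si != sj) {
            sets[[si]] <- union(sets[[si]], sets[[sj]])
            sets <- sets[-sj]
            changed <- TRUE
          }
        }
      }
    }
    out[[g]] <- lapply(sets, sort_allele_names)
  }
  out
}

partition_key <- function(part) {
  sort(unname(vapply(part, function(m) paste(sort(m), collapse = ","), "")))
}

groups_partition <- function(groups, gene) {
  lapply(strsplit(groups$members[groups$gene == gene], ",", fixed = TRUE),
         sort_allele_names)
}

# Exhaustive pair scan over all alleles: candidate display pairs for an
# observation set.
oracle_enumerate <- function(obs, db, panel, gene,
                             representative_override = NULL) {
  groups <- ambiguity_groups(db, panel,
                             representative_override = representative_override)
  dm <- group_display_map(groups)
  sigs <- oracle_signatures(db, panel)
  idx <- which(db$gene == gene)
  amps <- names(obs)
  found <- character(0)
  for (i in idx) for (j in idx) {
    if (i > j) next
    ok <- TRUE
    for (a in amps) {
      if (!length(obs[[a]])) next
      if (!setequal(c(sigs[[i]][a], sigs[[j]][a]), obs[[a]])) { ok <- FALSE; break }
    }
    if (ok) {
      d <- c(dm[[db$first_field[i]]], dm[[db$first_field[j]]])
      found <- c(found, paste(sort(d), collapse = "+"))
    }
  }
  sort(unique(found))
}

call_pair_keys <- function(call) {
  sort(vapply(call$pairs, function(p) paste(sort(p), collapse = "+"), ""))
}

noise_free_obs <- function(db, panel, a1, a2) {
  s1 <- project_allele(db[db$allele == a1, ], panel)
  s2 <- project_allele(db[db$allele == a2, ], panel)
  lapply(setNames(names(s1), names(s1)), function(a) unique(c(s1[a], s2[a])))
}
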