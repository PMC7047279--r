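# reads for one sample with known haplotypes, through the same simulator
# stream the cohort engine uses
reads_for_sample <- function(db, panel, alleles, depth, error_rate = 0,
                             seed = 1L, sample = 1L) {
  index <- build_typing_index(db, panel)
  r1 <- list(); r2 <- list()
  for (gi in seq_along(index$genes)) {
    gidx <- index$gene_index[[index$genes[gi]]]
    for (ai in seq_along(index$amps)) {
      for (h in 1:2) {
        al <- alleles[h]
        if (!al %in% gidx$alleles) next
        sig <- gidx$class_sig[gidx$class_of_allele[match(al, gidx$alleles)],
                              index$amps[ai]]
        pr <- micatype:::cpp_sim_pairs(sig, max(1L, depth %/% 2L), 249L,
                                       error_rate, seed, sample, gi, ai, h)
        r1[[length(r1) + 1L]] <- pr$r1
        r2[[length(r2) + 1L]] <- pr$r2
      }
    }
  }
  list(r1 = unlist(r1), r2 = unlist(r2))
}

test_that("genotype enumeration matches brute force on the constructed quartet", {
  panel <- two_amp_panel()
  s <- quartet_seqs()

  # three-allele database: only A+B explains ({x1,x2},{y1,y2})
  db3 <- quartet_db(include_d = FALSE)
  obs <- list(ex2 = c(s$x1, s$x2), ex3 = c(s$y1, s$y2))
  call3 <- enumerate_genotypes(obs, db3, panel, gene = "MICA")
  expect_equal(call_pair_keys(call3), "MICA*001+MICA*002")
  expect_false("phase_ambiguous" %in% call3$flags)
  expect_equal(call_pair_keys(call3), oracle_enumerate(obs, db3, panel, "MICA"))

  # with D = (x1, y2) the observation becomes phase-ambiguous: A+B | C+D
  db4 <- quartet_db(include_d = TRUE)
  call4 <- enumerate_genotypes(obs, db4, panel, gene = "MICA")
  expect_equal(call_pair_keys(call4),
               c("MICA*001+MICA*002", "MICA*003+MICA*004"))
  expect_true("phase_ambiguous" %in% call4$flags)
  expect_equal(call4$gl, "MICA*001+MICA*002|MICA*003+MICA*004")
  expect_equal(call_pair_keys(call4), oracle_enumerate(obs, db4, panel, "MICA"))

  # single variant on every amplicon: homozygote
  hom <- enumerate_genotypes(list(ex2 = s$x1, ex3 = s$y1), db4, panel, gene = "MICA")
  expect_equal(call_pair_keys(hom), "MICA*001+MICA*001")
})

test_that("enumeration equals the exhaustive pair scan on random databases", {
  panel <- two_amp_panel()
  set.seed(99)
  for (rep in 1:40) {
    db <- random_test_db(1000 + rep, n = 10L, twin_prob = 0.4)
    index <- build_typing_index(db, panel)
    i <- sample.int(nrow(db), 1); j <- sample.int(nrow(db), 1)
    obs <- noise_free_obs(db, panel, db$allele[i], db$allele[j])
    call <- enumerate_genotypes(obs, index = index, gene = "MICA")
    expect_equal(call_pair_keys(call), oracle_enumerate(obs, db, panel, "MICA"),
                 info = paste("rep", rep))
    # truth containment
    dm <- group_display_map(index$groups)
    truth_key <- paste(sort(c(dm[[db$first_field[i]]], dm[[db$first_field[j]]])),
                       collapse = "+")
    expect_true(truth_key %in% call_pair_keys(call), info = paste("rep", rep))
  }
})

test_that("novel observations are classified as sequence vs combination", {
  panel <- two_amp_panel()
  db <- quartet_db(include_d = FALSE)
  s <- quartet_seqs()

  # one substitution into a known projection
  mutated <- paste0("A", substr(s$y1, 2L, nchar(s$y1)))
  call <- enumerate_genotypes(list(ex2 = s$x1, ex3 = c(s$y1, mutated)),
                              db, panel, gene = "MICA")
  expect_length(call$pairs, 0L)
  expect_true("novel_sequence" %in% call$flags)
  expect_true(is.na(call$gl))

  # all sequences known but no allele carries (x1, y2): novel combination
  call2 <- enumerate_genotypes(list(ex2 = s$x1, ex3 = c(s$y1, s$y2)),
                               db, panel, gene = "MICA")
  expect_length(call2$pairs, 0L)
  expect_true("novel_combination" %in% call2$flags)

  expect_equal(classify_novel(list(ex2 = s$x1, ex3 = mutated), db, panel,
                              gene = "MICA"), "novel_sequence")
})

test_that("gene assignment prefers exact matches and errors on ties", {
  db <- make_german_reference_db()
  panel <- default_panel()
  index <- build_typing_index(db, panel)
  sig_b <- project_allele(db[db$allele == "MICB*008", ], panel)
  expect_equal(assign_gene(unname(sig_b["ex2"]), index = index), "MICB")

  sig_a <- project_allele(db[db$allele == "MICA*004", ], panel)
  near <- sub("A", "C", sig_a[["ex3"]])  # one substitution off a MICA projection
  expect_equal(assign_gene(near, index = index), "MICA")

  # a constructed collision fixture where a chimera is exactly equidistant
  toy <- allele_db(data.frame(
    gene = c("MICA", "MICB"), allele = c("MICA*001", "MICB*001"),
    exon2 = c(strrep("A", 20), strrep("T", 20)),
    exon3 = c(strrep("C", 20), strrep("G", 20)), stringsAsFactors = FALSE))
  toy_index <- build_typing_index(toy, two_amp_panel())
  chimera <- paste0(strrep("A", 10), strrep("T", 10))
  expect_error(assign_gene(chimera, index = toy_index),
               class = "micatype_ambiguous_gene")
})

test_that("noise-free reads give one exact variant per amplicon at full depth", {
  db <- make_german_reference_db("MICB")
  panel <- default_panel()
  reads <- reads_for_sample(db, panel, c("MICB*008", "MICB*008"), depth = 100)
  obs <- call_amplicons(reads$r1, reads$r2, db, panel)
  expect_equal(nrow(obs), 3L)
  expect_equal(obs$count, rep(100L, 3))
  expect_false(any(obs$low_coverage))
  sig <- project_allele(db[db$allele == "MICB*008", ], panel)
  expect_setequal(obs$seq, unname(sig))
})

test_that("a 1%-error heterozygote yields exactly two variants per differing amplicon", {
  db <- make_german_reference_db("MICB")
  panel <- default_panel()
  reads <- reads_for_sample(db, panel, c("MICB*002", "MICB*005:02"),
                            depth = 1000, error_rate = 0.01, seed = 5L)
  obs <- call_amplicons(reads$r1, reads$r2, db, panel)
  sig2 <- project_allele(db[db$allele == "MICB*002", ], panel)
  sig5 <- project_allele(db[db$allele == "MICB*005:02", ], panel)
  for (a in c("ex2", "ex3")) {   # the two alleles differ on ex2 and ex3 only
    oa <- obs[obs$amplicon == a, ]
    expect_equal(nrow(oa), 2L, info = a)
    expect_setequal(oa$seq, unique(c(sig2[[a]], sig5[[a]])))
  }
  oa45 <- obs[obs$amplicon == "ex4-5", ]
  expect_equal(nrow(oa45), 1L)
  expect_equal(oa45$seq, unname(sig2["ex4-5"]))

  ts <- type_sample(r1 = reads$r1, r2 = reads$r2, db = db, panel = panel)
  expect_equal(ts$MICB$gl, "MICB*002+MICB*005#|MICB*018+MICB*019")
})

test_that("low-coverage amplicons are flagged and exon-2/3 fallback applies", {
  db <- make_german_reference_db("MICB")
  panel <- default_panel()
  index <- build_typing_index(db, panel)
  # drop the ex4-5 reads entirely (amplicon dropout)
  reads <- reads_for_sample(db, panel, c("MICB*002", "MICB*002"), depth = 100)
  sig <- project_allele(db[db$allele == "MICB*002", ], panel)
  keep <- !startsWith(reads$r1, substr(sig[["ex4-5"]], 1, 30))
  ts <- type_sample(r1 = reads$r1[keep], r2 = reads$r2[keep], db = db,
                    panel = panel)
  expect_true(all(c("exon23_only", "low_coverage_retest") %in% ts$MICB$flags))
  expect_equal(call_pair_keys(ts$MICB), "MICB*002+MICB*002")

  # 10 reads on ex4-5 against min_depth 50: only that amplicon is low
  reads2 <- reads_for_sample(db, panel, c("MICB*008", "MICB*008"), depth = 100)
  drop45 <- which(startsWith(reads2$r1, substr(project_allele(
    db[db$allele == "MICB*008", ], panel)[["ex4-5"]], 1, 30)))
  drop45 <- drop45[-(1:10)]
  obs <- call_amplicons(reads2$r1[-drop45], reads2$r2[-drop45], index = index)
  expect_equal(obs$low_coverage[obs$amplicon == "ex4-5"], TRUE)
  expect_false(any(obs$low_coverage[obs$amplicon != "ex4-5"]))
})

test_that("exon-2/3 fallback candidates contain the full-panel candidates", {
  db <- make_german_reference_db("MICB")
  panel <- default_panel()
  index <- build_typing_index(db, panel,
                              representative_override = db_representative_override(db))
  set.seed(123)
  alleles <- db$allele
  for (rep in 1:50) {
    pair <- sample(alleles, 2, replace = TRUE)
    obs <- noise_free_obs(db, panel, pair[1], pair[2])
    full <- enumerate_genotypes(obs, index = index, gene = "MICB")
    fb <- exon23_fallback(obs, index = index, gene = "MICB")
    expect_true("exon23_only" %in% fb$flags)
    expect_true(all(call_pair_keys(full) %in% call_pair_keys(fb)),
                info = paste(pair, collapse = "+"))
  }
})

test_that("calls are invariant under haplotype swap and read shuffling", {
  db <- make_german_reference_db("MICB")
  panel <- default_panel()
  reads <- reads_for_sample(db, panel, c("MICB*004", "MICB*013"),
                            depth = 60, error_rate = 0.01, seed = 9L)
  base <- type_sample(r1 = reads$r1, r2 = reads$r2, db = db, panel = panel)
  set.seed(1)
  perm <- sample(length(reads$r1))
  shuf <- type_sample(r1 = reads$r1[perm], r2 = reads$r2[perm], db = db,
                      panel = panel)
  expect_equal(shuf$MICB$gl, base$MICB$gl)
  swap <- reads_for_sample(db, panel, c("MICB*013", "MICB*004"),
                           depth = 60, error_rate = 0.01, seed = 9L)
  swapped <- type_sample(r1 = swap$r1, r2 = swap$r2, db = db, panel = panel)
  expect_equal(swapped$MICB$gl, base$MICB$gl)
})
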