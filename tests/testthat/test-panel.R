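test_that("projection restricts alleles to covered intervals", {
  db <- allele_db(data.frame(
    gene = "MICA", allele = "MICA*001",
    exon2 = strrep("A", 255), exon3 = strrep("C", 288),
    exon4 = paste0(strrep("G", 65), strrep("T", 215)),
    exon5 = paste0(strrep("A", 87), strrep("C", 13)),
    stringsAsFactors = FALSE))
  sig <- project_allele(db[1, ], default_panel())
  expect_equal(unname(nchar(sig[c("ex2", "ex3", "ex4-5")])), c(255L, 288L, 302L))
  expect_equal(unname(sig["ex2"]), strrep("A", 255))       # full coverage = verbatim
  expect_equal(unname(sig["ex4-5"]), paste0(strrep("T", 215), strrep("A", 87)))

  # exon-4/5 covered length: (len4 - 65) + (len5 - 13)
  db2 <- allele_db(data.frame(
    gene = "MICA", allele = "MICA*002", exon2 = "ACGT", exon3 = "ACGT",
    exon4 = strrep("A", 280), exon5 = strrep("C", 100), stringsAsFactors = FALSE))
  sig2 <- project_allele(db2[1, ], default_panel())
  expect_equal(unname(nchar(sig2["ex4-5"])), (280L - 65L) + (100L - 13L))

  # missing exon -> projection error
  db3 <- allele_db(data.frame(gene = "MICA", allele = "MICA*003",
                              exon2 = "ACGT", exon3 = "ACGT",
                              exon4 = strrep("A", 280), stringsAsFactors = FALSE))
  expect_error(project_allele(db3[1, ], default_panel()),
               class = "micatype_projection_error")
  expect_error(allele_signatures(db3, default_panel(), on_error = "error"))
  expect_warning(s <- allele_signatures(db3, default_panel(), on_error = "drop"),
                 "excluded")
  expect_equal(nrow(s), 0L)
})

test_that("panel YAML round-trips", {
  p <- default_panel()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_panel(p, f)
  p2 <- read_panel(f)
  expect_equal(p2, p)
})

test_that("exon-6-only differences merge into one hash group", {
  db <- allele_db(data.frame(
    gene = "MICB",
    allele = c("MICB*001", "MICB*002", "MICB*003"),
    exon2 = c("AAAA", "CCCC", "AAAA"),
    exon3 = c("GGGG", "GGGG", "GGGG"),
    exon6 = c("TTTT", "TTTT", "TTTA"),   # *003 differs from *001 only here
    stringsAsFactors = FALSE))
  g <- ambiguity_groups(db, two_amp_panel())
  expect_equal(g$display, c("MICB*001#", "MICB*002"))
  expect_equal(g$members[1], "MICB*001,MICB*003")
  expect_equal(sum(g$n_members), 3L)
})

test_that("pairwise-distinct signatures give all singleton groups", {
  db <- random_test_db(21, n = 6L, twin_prob = 0)
  g <- ambiguity_groups(db, two_amp_panel())
  expect_true(all(g$n_members == 1L))
  expect_false(any(grepl("#", g$display, fixed = TRUE)))
})

test_that("ambiguity groups equal the brute-force signature partition", {
  panel <- two_amp_panel()
  for (seed in 1:30) {
    db <- random_test_db(seed, n = sample(c(5L, 8L, 20L), 1L))
    g <- ambiguity_groups(db, panel)
    expect_identical(partition_key(groups_partition(g, "MICA")),
                     partition_key(oracle_ambiguity_partition(db, panel)$MICA),
                     info = paste("seed", seed))
  }
})

test_that("representative override changes the display name", {
  db <- allele_db(data.frame(
    gene = "MICB", allele = c("MICB*003", "MICB*005", "MICB*008"),
    exon2 = c("AAAA", "AAAA", "CCCC"), exon3 = "GGGG",
    exon6 = c("TT", "TA", "TT"), stringsAsFactors = FALSE))
  g0 <- ambiguity_groups(db, two_amp_panel())
  expect_equal(g0$display[g0$n_members == 2L], "MICB*003#")
  g1 <- ambiguity_groups(db, two_amp_panel(),
                         representative_override = c("MICB*003" = "MICB*005"))
  expect_equal(g1$display[g1$n_members == 2L], "MICB*005#")
  expect_error(ambiguity_groups(db, two_amp_panel(),
                                representative_override = c("MICB*003" = "MICB*008")),
               "not a member")
})

test_that("coverage refinement only splits groups, never merges", {
  # full panel (ex2+ex3) partitions must refine the ex2-only partitions
  sub_panel <- amplicon_panel(list(
    list(name = "ex2", segments = data.frame(exon = 2L, start = 0L))), "sub")
  for (seed in 31:45) {
    db <- random_test_db(seed, n = 10L, twin_prob = 0.5)
    full <- groups_partition(ambiguity_groups(db, two_amp_panel()), "MICA")
    sub <- groups_partition(ambiguity_groups(db, sub_panel), "MICA")
    # every full-panel group must be contained in a single sub-panel group
    for (grp in full) {
      container <- vapply(sub, function(s) all(grp %in% s), logical(1))
      expect_equal(sum(container), 1L, info = paste("seed", seed))
    }
  }
})

test_that("cross-gene projection collisions are reported", {
  tab <- data.frame(
    gene = c("MICA", "MICB"), allele = c("MICA*001", "MICB*001"),
    exon2 = c("AAAATTTT", "CCCCGGGG"), exon3 = c("GGGG", "TTTT"),
    stringsAsFactors = FALSE)
  rep0 <- cross_gene_disjointness(allele_db(tab), two_amp_panel())
  expect_true(attr(rep0, "disjoint"))
  expect_equal(nrow(rep0), 0L)

  tab$exon2[2] <- tab$exon2[1]  # copy a MICA projection into MICB
  rep1 <- cross_gene_disjointness(allele_db(tab), two_amp_panel())
  expect_false(attr(rep1, "disjoint"))
  expect_equal(rep1$amplicon, "ex2")
  expect_equal(rep1$alleles_a, "MICA*001")
})
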