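test_that("synthetic databases are deterministic and carry the engineered fixtures", {
  db1 <- make_synthetic_db(seed = 7)
  db2 <- make_synthetic_db(seed = 7)
  expect_identical(as.data.frame(db1), as.data.frame(db2))
  db3 <- make_synthetic_db(seed = 8)
  expect_false(identical(as.data.frame(db1), as.data.frame(db3)))

  panel <- default_panel()
  g <- ambiguity_groups(db1, panel)
  for (gene in c("MICA", "MICB")) {
    gg <- g[g$gene == gene, ]
    expect_equal(sum(gg$n_members > 1L), 1L)   # exactly one engineered twin group
    expect_equal(gg$n_members[gg$n_members > 1L], 2L)
  }
  expect_true(attr(cross_gene_disjointness(db1, panel), "disjoint"))

  # quartet: het P1+P2 is phase-ambiguous with P3+P4
  obs <- noise_free_obs(db1, panel, "MICA*001", "MICA*002")
  call <- enumerate_genotypes(obs, db1, panel, gene = "MICA")
  expect_true("phase_ambiguous" %in% call$flags)
  expect_equal(call_pair_keys(call),
               c("MICA*001+MICA*002", "MICA*003+MICA*004"))

  # fixtures off: all singleton groups, no ambiguity
  db0 <- make_synthetic_db(seed = 7, fixtures = list())
  g0 <- ambiguity_groups(db0, panel)
  expect_true(all(g0$n_members == 1L))
})

test_that("cohort draws follow the configured Hardy-Weinberg frequencies", {
  db <- make_german_reference_db()
  cfg <- simulation_config(seed = 42, n_samples = 20000L, novel_rate = 0)
  cohort <- sample_cohort(db, cfg)
  truth <- cohort$truth
  fa <- renormalize_frequencies(german_allele_frequencies("MICA"))
  ta <- truth[truth$gene == "MICA", ]
  draws <- c(ta$group1, ta$group2)
  for (grp in c("MICA*008", "MICA*002")) {
    p <- fa[[grp]]
    se <- sqrt(p * (1 - p) / length(draws))
    expect_lt(abs(mean(draws == grp) - p), 3 * se)
  }
  # genotype-level HWE: homozygosity rate of the top group ~ p^2
  p8 <- fa[["MICA*008"]]
  hom <- mean(ta$group1 == "MICA*008" & ta$group2 == "MICA*008")
  expect_lt(abs(hom - p8^2), 3 * sqrt(p8^2 * (1 - p8^2) / nrow(ta)))
})

test_that("novel injection hits the configured per-sample rate", {
  db <- make_german_reference_db()
  cfg <- simulation_config(seed = 11, n_samples = 30000L, novel_rate = 0.005)
  cohort <- sample_cohort(db, cfg)
  frac <- length(unique(cohort$novel_alleles$sample)) / cfg$n_samples
  se <- sqrt(0.005 * 0.995 / cfg$n_samples)
  expect_lt(abs(frac - 0.005), 3 * se)
  # injected copies differ from their base allele only at covered positions
  panel <- default_panel()
  nov <- cohort$novel_alleles
  for (i in seq_len(min(20L, nrow(nov)))) {
    base <- db[db$allele == nov$base_allele[i], ]
    expect_false(identical(project_allele(nov[i, ], panel),
                           project_allele(base, panel)))
    expect_identical(nov$exon6[i], base$exon6)
  }
})

test_that("read synthesis is deterministic and error-free reads are exact", {
  db <- make_german_reference_db("MICB")
  cfg <- simulation_config(seed = 5, n_samples = 3L, genes = "MICB",
                           depth = 20L, error_rate = 0, novel_rate = 0)
  cohort <- sample_cohort(db, cfg)
  panel <- default_panel()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  synthesize_reads(cohort, db, panel, dir = d1)
  synthesize_reads(cohort, db, panel, dir = d2)
  expect_identical(readLines(file.path(d1, "reads_R1.fastq")),
                   readLines(file.path(d2, "reads_R1.fastq")))

  reads <- read_paired_fastq(file.path(d1, "reads_R1.fastq"),
                             file.path(d1, "reads_R2.fastq"))
  expect_equal(sort(unique(reads$sample)), 1:3)
  sigs <- allele_signatures(db, panel)
  all_sigs <- unlist(sigs[, panel_amplicon_names(panel)])
  in_some_amplicon <- vapply(reads$r1[1:50], function(r)
    any(startsWith(all_sigs, r)), logical(1))
  expect_true(all(in_some_amplicon))
})

test_that("simulated per-read error rates match the configured rate", {
  db <- make_german_reference_db("MICB")
  panel <- default_panel()
  sig <- project_allele(db[db$allele == "MICB*008", ], panel)[["ex2"]]
  pr <- micatype:::cpp_sim_pairs(sig, 2000L, 249L, 0.02, 77L, 1L, 1L, 1L, 1L)
  mm <- sum(vapply(pr$r1, function(r)
    sum(utf8ToInt(r) != utf8ToInt(substr(sig, 1, 249))), numeric(1)))
  rate <- mm / (2000 * 249)
  se <- sqrt(0.02 * 0.98 / (2000 * 249))
  expect_lt(abs(rate - 0.02), 4 * se)
})

test_that("amplicons longer than paired reads can span are rejected", {
  db <- allele_db(data.frame(
    gene = "MICA", allele = "MICA*001",
    exon2 = strrep("A", 600), exon3 = "ACGT", stringsAsFactors = FALSE))
  panel <- amplicon_panel(list(
    list(name = "ex2", segments = data.frame(exon = 2L, start = 0L))))
  cfg <- simulation_config(seed = 1, n_samples = 1L, genes = "MICA",
                           frequencies = list(MICA = c("MICA*001" = 1)),
                           depth = 10L, error_rate = 0, novel_rate = 0)
  cohort <- sample_cohort(db, cfg, panel)
  expect_error(synthesize_reads(cohort, db, panel), "exceeds 2 x read length")
})

test_that("truth tables round-trip through TSV", {
  db <- make_german_reference_db("MICA")
  cfg <- simulation_config(seed = 2, n_samples = 5L, genes = "MICA",
                           novel_rate = 0)
  cohort <- sample_cohort(db, cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth(cohort, f)
  back <- read_truth(f)
  expect_equal(back$allele1, cohort$truth$allele1)
  expect_equal(back$group2, cohort$truth$group2)
})
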