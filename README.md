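# micatype

High-throughput genotyping of the NKG2D-ligand genes **MICA** and **MICB**
from a three-amplicon short-read panel, with ambiguity-aware cohort
allele-frequency estimation.

## The problem

MICA and MICB are HLA-like, highly polymorphic MHC genes whose products are
stress-induced ligands of the NKG2D receptor on NK and T cells. Matching
them between donor and patient is of growing interest in unrelated
hematopoietic stem cell transplantation, which calls for registry-scale
genotyping at minimal cost. A practical design amplifies exons 2 and 3
completely and exons 4/5 as one joined amplicon whose primers sit inside
the exons, leaving the first 65 bases of exon 4 and the last 13 bases of
exon 5 (plus exons 1 and 6) unsequenced. That economy has two structural
consequences the analysis must handle explicitly:

1. **Allele ambiguity.** Alleles that differ only in uncovered regions are
   indistinguishable and must be reported as a group (written with a
   trailing `#`, e.g. `MICB*005#` for MICB\*003/005/006/010).
2. **Phasing ambiguity.** The short amplicons cannot be phased against each
   other, so an unphased set of per-amplicon sequences can be explained by
   more than one allele pair — classically
   `MICB*002+MICB*005#|MICB*018+MICB*019` in GL-string notation.

`micatype` implements the full analysis path: allele-database projection
onto the covered panel, per-amplicon variant calling from paired-end reads,
exhaustive genotype enumeration at ambiguity-group resolution, novel-allele
flagging, statistical resolution of phasing ambiguities, GL-string export,
and cohort allele-frequency estimation — plus a synthetic-data module so
every step can be exercised end to end with no external data.

## The statistics at the core

For an unphased observation *O* (one or two sequence variants per
amplicon), the candidate set is every unordered allele pair (a, b) with
{sig(a), sig(b)} = O on **every** amplicon, where sig(·) is the allele's
projection onto the covered regions; candidates are collapsed to
ambiguity-group pairs. When more than one pair survives, alternatives are
ranked by their Hardy–Weinberg genotype probability under allele-group
frequencies f estimated from unambiguously typed samples,

  P(g1, g2) = 2·f(g1)·f(g2)  (g1 ≠ g2),  P(g, g) = f(g)²,

and an alternative is discarded when it is at least 1000-fold less likely
than the best explanation; the discarded probability mass is recorded as
the call's expected error. For cohort frequencies, unambiguous (and
threshold-resolved) genotypes contribute integer allele counts
(homozygotes count twice); each remaining ambiguous sample contributes two
fractional counts split across its candidate pairs in proportion to their
normalized HWE probabilities (optionally iterated as an EM until the
frequencies are stationary). Counts per gene always sum to exactly twice
the number of samples used.

## Worked example

```r
library(micatype)

db    <- make_german_reference_db()   # synthetic DB with the real ambiguity structure
panel <- default_panel()

# the panel-induced ambiguity groups
subset(ambiguity_groups(db, panel,
       representative_override = db_representative_override(db)), n_members > 1)
#>    gene representative   display                             members n_members
#> 6  MICA       MICA*009 MICA*009#                   MICA*009,MICA*049         2
#> 7  MICA       MICA*010 MICA*010#          MICA*010,MICA*065,MICA*069         3
#> 15 MICA       MICA*027 MICA*027#                   MICA*027,MICA*048         2
#> 17 MICB       MICB*004 MICB*004#                   MICB*004,MICB*028         2
#> 18 MICB       MICB*005 MICB*005# MICB*003,MICB*005,MICB*006,MICB*010         4
#> 21 MICB       MICB*014 MICB*014#                   MICB*014,MICB*015         2

# a heterozygote that hits the dominant MICB phasing ambiguity
sig2 <- project_allele(db[db$allele == "MICB*002", ], panel)
sig5 <- project_allele(db[db$allele == "MICB*005:02", ], panel)
obs  <- lapply(setNames(nm = names(sig2)), function(a) unique(c(sig2[[a]], sig5[[a]])))
call <- enumerate_genotypes(obs, db, panel, gene = "MICB")
call$gl
#> [1] "MICB*002+MICB*005#|MICB*018+MICB*019"

# resolve it against the German group frequencies
prior <- frequency_prior(list(MICB = renormalize_frequencies(
  german_allele_frequencies("MICB"))))
rc <- resolve_phasing(call, prior, odds_threshold = 1000)
rc
#> resolved_call: MICB*002+MICB*005#
#>   2 candidate(s), 1 retained; expected_error = 1.14e-07

# full closed loop: simulate -> type -> resolve -> estimate
loop <- run_closed_loop("MICB", n_samples = 2000, seed = 7,
                        depth = 100, error_rate = 0.01)
head(loop$recovery, 4)
#>   gene     group  truth estimate       se within_3se
#> 1 MICB MICB*005# 0.4429   0.4470 0.007854       TRUE
#> 2 MICB MICB*004# 0.2189   0.2157 0.006538       TRUE
#> 3 MICB  MICB*002 0.1907   0.1895 0.006211       TRUE
#> 4 MICB  MICB*008 0.1110   0.1077 0.004966       TRUE
```

`loop$recovery` compares the estimated group frequencies with the
simulation truth; `within_3se` marks agreement within three binomial
standard errors. `loop$summary` reports how many samples were
phase-ambiguous (≈17% for MICB, dominated by the MICB\*002 + MICB\*005#
heterozygote) and that all of them were statistically resolved.

A thin command-line wrapper with subcommands `simulate`, `type`, `freq`,
`ambigmap` and `demo` is installed under `inst/scripts/micatype`.

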