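---
title: "Genotyping MICA and MICB from a three-amplicon panel: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping MICA and MICB from a three-amplicon panel: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micatype)
```

## The assay and what it can and cannot see

MICA and MICB are polymorphic MHC-encoded ligands of the NKG2D receptor.
Registry-scale genotyping of both genes is practical with a single
multiplexed PCR producing three amplicons per gene: exon 2 and exon 3
complete, and exons 4/5 as one joined amplicon whose primers sit inside
the exons. Under the default panel (`default_panel()`), the first 65 bases
of exon 4 and the last 13 bases of exon 5 are therefore uncovered, and
exons 1 and 6 are not part of the assay at all. Amplicons are sequenced as
overlapping 2 × 249 bp read pairs.

Everything in this package follows from taking that coverage seriously.
An allele is represented by its *signature*: the tuple of its sequences
projected onto the covered intervals (`project_allele()`). Two
protein-level (first-field) allele groups that share a signature on every
amplicon are fused into an *ambiguity group*, displayed as a
representative name plus `#` (`ambiguity_groups()`). The packaged
synthetic reference database (`make_german_reference_db()`) engineers
exactly the group structure this panel induces on the real allele
catalogue — MICA\*009#, MICA\*010#, MICA\*027#, MICB\*004#, MICB\*005#,
MICB\*014# — including the instructive edge case that MICA\*009:02 differs
from MICA\*049 inside exon 3 and is therefore typable even though
MICA\*009:01 is not. One reporting convention cannot be derived from any
sorting rule: the MICB\*003/005/006/010 group is customarily displayed as
`MICB*005#` although MICB\*003 is the alphabetically smallest member. The
representative policy is therefore "smallest member" with an explicit
override map, stored on the database object.

## Genotype enumeration

Per sample and gene the assay yields one or two sequence variants per
amplicon, unphased across amplicons. The matching contract
(`enumerate_genotypes()`) is deliberately exact: a candidate genotype is
an unordered allele pair (a, b) such that on **every** amplicon the set
{sig(a), sig(b)} equals the observed variant set; a single observed
variant requires both alleles to carry it. Candidates are reported at
ambiguity-group resolution and exported as a GL string (`+` within a
genotype, `|` between alternatives). Near-matches are never silently
accepted: if no pair is consistent, the call is flagged `novel_sequence`
(some observed variant matches no known projection) or
`novel_combination` (all variants known, but no allele pairs them that
way), both of which are retest semantics rather than calls. The
implementation filters candidate alleles per amplicon and then checks the
pair condition; the test suite holds it equal to a brute-force scan over
all pairs on randomized databases.

When coverage fails only on the joined exon-4/5 amplicon, typing can fall
back to exons 2 and 3 (`exon23_fallback()`); the resulting candidate set
provably contains the full-panel one, and such calls carry an
`exon23_only` flag.

## Variant calling from reads

Read pairs are merged by overlap (the amplicon length is chosen among the
panel's known projected lengths by minimum overlap mismatch; where the two
reads of a pair disagree inside the overlap, R1's base is kept — with no
per-base quality model there is no better arbiter, and the choice only
matters at the per-position error rate). Merged reads are assigned to the
nearest gene/amplicon reference by prefix Hamming distance with a mismatch
cap; ties are dropped.

Variants are then called positionally (`call_amplicons()`): column-wise
base counts over the merged-read stack give a consensus; a column is
heterozygous when its minor-base fraction reaches `min_minor_fraction`
(default 0.25) with at least two supporting reads; and the per-read base
patterns across the heterozygous columns — which are phased *within* an
amplicon because each merged read spans it — define at most two variants
and their read counts. This matters quantitatively: at the default 1%
substitution error and ~300 bp amplicons, only ~5% of reads are error-free,
so clustering exact read sequences would leave the true variant supported
by a handful of reads and indistinguishable from error singletons at
depth 100. Column-wise calling instead faces, per column, a
Binomial(depth, 0.01) error count against a ~50% true minor fraction; at
depth 100 the two distributions are separated by many standard deviations,
so both false heterozygous columns and missed ones are vanishingly rare,
and the emitted consensus variants are exact. Amplicons with fewer than
`min_depth` (default 50) merged reads are flagged for retest rather than
called.

These thresholds are calibrated to the simulated study conditions
(depth 100–1000, error ≤ 1%); they are not estimates of any production
system's internal thresholds, which are not public.

## Resolving phasing ambiguities

Short amplicons cannot be phased against each other, so some observations
admit two explanations; on this panel the dominant case is
`MICB*002+MICB*005#|MICB*018+MICB*019`, which arises in every
MICB\*002 + MICB\*005# heterozygote (~17% of samples at German
frequencies). `resolve_phasing()` ranks the alternatives by their
Hardy–Weinberg probability — 2·f₁·f₂ for heterozygotes, f² for homozygotes,
no inbreeding term, genes treated independently — under a prior estimated
from unambiguously typed samples, and discards an alternative when it is
at least `odds_threshold` (default 1000) times less likely than the best
one. The probability mass of everything discarded, normalized over the
candidate set, is stored as `expected_error`; it is the per-call
probability that the discarded explanation was in fact the truth, and the
cohort sum of `expected_error` bounds the expected number of wrong calls
introduced by thresholding. With German-like frequency spectra the
dominant MICB ambiguity resolves with expected error around 5×10⁻⁸–10⁻⁶,
which is why discarding the rare-pair explanation is safe while discarding
the *samples* would not be (they carry ~17% of all MICB\*002 copies).
Groups absent from the prior receive a floor pseudo-frequency (default
10⁻⁵, the order of one observation in a 10⁵-allele cohort) so no
explanation is excluded with probability zero; if *every* candidate sits
at the floor the call is left unresolved with a warning.

The threshold value 1000 is a design choice: large enough that resolution
is effectively reserved for rare–rare versus common–common contrasts
(odds ratios in the 10⁵–10⁷ range), small enough to act on all of them.

## Frequency estimation

`allocate_ambiguous()` builds the cohort table: unambiguous samples —
including, by default, threshold-resolved ones — contribute integer
counts (homozygotes count twice); each remaining ambiguous sample
contributes two fractional counts split across its candidate genotypes
proportionally to their normalized HWE probabilities under the prior.
Count conservation (per gene, Σ counts = 2 × samples used) holds exactly
at every step and is asserted in code. `mode = "em"` re-derives the prior
from the current table and iterates to stationarity (tolerance 10⁻⁸,
default cap 200 iterations); `mode = "single_pass"` is the default and
equals the first EM iteration — the two-step procedure (provisional
frequencies from unambiguous samples, then one probabilistic allocation)
is the primary contract, with EM as an opt-in refinement. Dropping
ambiguous samples instead would bias the involved groups materially
(MICB\*002 by about −6 percentage points at German frequencies); the test
suite demonstrates both the bias and that allocation removes essentially
all of it. A rare-call audit (`rare_allele_audit()`) lists every group
observed fewer than 50 times and requires two distinct verified samples
for confirmation.

## The synthetic-data module

`make_synthetic_db()` / `make_german_reference_db()` build exon-level
allele databases from random base sequences per gene, with substitutions
at distinct covered positions guaranteeing distinct signatures except
where a fixture engineers a collision: exon-6 (or uncovered exon-4) twins
reproduce the hash groups, and a four-allele quartet with crossed exon-2 /
exon-3 variant patterns reproduces the phasing ambiguity
(sig(P1) ∪ sig(P2) = sig(P3) ∪ sig(P4) per amplicon). Genes get
independent random backgrounds, so cross-gene projection disjointness —
the property that lets reads be assigned to a gene unambiguously — holds
by construction and is verified, not assumed.

`sample_cohort()` draws diploid genotypes i.i.d. under Hardy–Weinberg
equilibrium from a group-frequency table. The default table is the German
registry spectrum: MICA\*008 42.3%, MICA\*002 11.7%, MICA\*009# 8.8%,
MICA\*010# 7.7%, MICA\*004 6.5% (the 15 most common groups cumulating to
99.5%), and MICB\*005# 43.9%, MICB\*004# 21.7%, MICB\*002 18.9%,
MICB\*008 11.0%, MICB\*014# 2.2%, MICB\*013 1.4%. Only those values are
reported by the registry survey; the ten-group MICA tail is modeled with
plausible European values filling the remainder to the stated cumulative,
and the MICB tail models MICB\*018 = 1.9×10⁻⁴ and MICB\*019 = 5×10⁻⁵ so
that the 018/019 heterozygote probability equals the reported 1.9×10⁻⁸.
Each table is renormalized to sum to 1 over the modeled groups, which
preserves ratios and shifts the truth ~0.2–0.4 pp above the reported
values; `german_allele_frequencies()` labels reported versus modeled rows.
Novel alleles are injected per sample with probability 0.005 (one
haplotype replaced by a copy carrying 1–3 substitutions at covered
positions, so novelty is detectable by design; a switch moves them to
uncovered positions to study the false-negative case).

`synthesize_reads()` emits 2 × 249 bp pairs covering each amplicon from
both ends at depth/2 pairs per haplotype with i.i.d. substitution errors
(no indels, no quality model — sufficient to exercise the threshold
contract; indel realism is out of scope). Read simulation uses its own
deterministic counter-seeded RNG, so the FASTQ path and the in-memory
cohort engine (`type_cohort()`) produce byte-identical reads and,
provably in the tests, identical calls.

What passing on this simulator does **not** show: robustness to indel
sequencing errors, PCR chimeras or stutter, index hopping, quality-score
artefacts, or allele catalogues whose exon lengths differ across alleles
of one gene. The matching and estimation layers are agnostic to all of
these; the read-level caller is where real data would add failure modes.

## Numerical and design notes

* Coordinates are 0-based half-open and exon-relative; primer sequences
  are not modeled, only the coverage they induce.
* Allele ordering (for representatives, GL canonicalization, stable
  output) is numeric field-by-field, with `N`-suffixed alleles directly
  after their numeric equal.
* `expected_error` is computed as the normalized discarded mass directly
  (not `1 − retained`) to avoid cancellation at the 10⁻⁷ scale.
* HWE weights in allocation use the current iterate's frequencies where
  positive and the floor otherwise, so no candidate genotype ever
  receives an exactly-zero weight.
* Ties in variant-pattern counts are broken lexicographically; candidate
  amplicon lengths in pair merging are tried in increasing order, so all
  calling is order-insensitive (asserted under read shuffling and
  haplotype swap).
* The database's release label is opaque metadata; the package does not
  parse genomic flat files — a documented exon-table (TSV) and a
  per-exon FASTA are the canonical formats.

## Problem sizes

The shipped test suite runs the full closed loop at n = 100,000 samples
per gene for the recovery checks (depth 100, error 1%), n = 20,000 for the
novel-detection rate, and smaller cohorts (200–20,000) for property
checks; `scripts/acceptance.R` reproduces the headline numbers at
n = 100,000 per run. These sizes give binomial standard errors of ~0.1 pp
on the major group frequencies, small enough that a biased estimator
would fail the 3-SE recovery bands by orders of magnitude.
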