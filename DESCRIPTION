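Package: micatype
Title: Amplicon-Based MICA and MICB Genotyping and Allele-Frequency
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genotyping of the NKG2D-ligand genes MICA and MICB from a
    three-amplicon short-read panel (exons 2, 3 and a joined 4/5 amplicon).
    Projects allele databases onto the covered regions, enumerates all
    allele pairs consistent with unphased per-amplicon sequences, collapses
    indistinguishable alleles into hash-marked ambiguity groups, resolves
    phasing ambiguities with Hardy-Weinberg genotype likelihoods, flags
    novel alleles, exports Genotype List (GL) strings, and estimates cohort
    allele-group frequencies with fractional allocation of ambiguous calls.
    Includes a synthetic-data module (allele databases with engineered
    ambiguity structure, Hardy-Weinberg cohorts, paired-end amplicon reads)
    so the complete pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
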