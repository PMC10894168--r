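Package: drugtargetmr
Title: Drug-Target Mendelian Randomization from GWAS Summary Statistics
Version: 1.0.0
Authors@R:
    person("drugtargetmr", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-sample Mendelian randomization toolkit for drug-target
    analyses built on GWAS summary statistics. Selects cis instruments for
    lipid-lowering drug-target genes (PCSK9, HMGCR, NPC1L1) from LDL
    cholesterol associations with p-value and linkage-disequilibrium
    clumping, harmonizes exposure and outcome records onto a shared effect
    allele, and estimates causal effects with inverse-variance-weighted
    (multiplicative random effects), MR-Egger, weighted-median and
    weighted-mode estimators, together with Cochran's Q heterogeneity,
    leave-one-out diagnostics, instrument-strength F statistics and a
    trait-association pleiotropy screen. Ships a published instrument table
    as a fixture and a synthetic two-sample GWAS generator with known
    ground truth, so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
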