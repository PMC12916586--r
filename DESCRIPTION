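Package: hlacc
Title: Case-Control Association Analysis for Multi-Allelic HLA Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for case-control association analysis of highly polymorphic
    HLA loci from unphased genotype tables: allele frequency estimation by
    direct gene counting, per-allele 2x2 association statistics with
    Haldane-Anscombe zero-cell handling, Woolf confidence intervals for odds
    ratios, Fisher's exact test, Sidak-type locus-wise multiplicity
    correction, Haberman adjusted standardized residuals, a Monte-Carlo exact
    Hardy-Weinberg test for multi-allelic loci, EM haplotype-frequency
    estimation from unphased genotypes with multi-allelic linkage
    disequilibrium summaries (mean |D'|, r-squared), and a synthetic-cohort
    simulator for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
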