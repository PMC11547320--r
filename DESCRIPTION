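Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end toolkit for two-sample Mendelian randomization
    (MR) with genome-wide association study (GWAS) summary statistics:
    instrument selection with greedy linkage-disequilibrium clumping and
    per-variant F-statistics, allele harmonization with palindromic-variant
    removal, a suite of causal estimators (Wald ratio, inverse-variance
    weighted with multiplicative random effects, penalized debiased IVW,
    MR-Egger, weighted median, weighted mode, MR-PRESSO outlier detection,
    leave-one-out), single-region Bayesian colocalization with approximate
    Bayes factors, fixed-effect meta-analysis across outcome GWAS with
    Cochran's Q and I-squared, sex-difference heterogeneity tests,
    Bonferroni-based significance classification, and power calculations
    for binary outcomes. A synthetic GWAS summary-statistics generator
    with recorded ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'summaryStats.R'
    'instruments.R'
    'estimators.R'
    'coloc.R'
    'metaPower.R'
    'syntheticData.R'
    'pipeline.R'
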