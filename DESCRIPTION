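Package: duogenie
Title: Maternal-Adjusted Fetal Genetic Effects on Birth Weight from
    GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the effect of fetal genetic
    predisposition to adult adiposity traits on birth weight and other
    perinatal outcomes. Partitions raw genome-wide association study
    (GWAS) effects on own and offspring birth weight into
    maternal-genotype-adjusted fetal and fetal-adjusted maternal
    components via a weighted linear model, harmonizes summary
    statistics to the adiposity-raising allele (resolving allele
    swaps, strand flips and palindromic variants), pools per-allele
    effects across SNP instrument sets with fixed- and random-effects
    (DerSimonian-Laird) meta-analysis including Cochran's Q, tau-squared
    and I-squared heterogeneity statistics, and tests dose-response
    proportionality of SNP effects with inverse-variance-weighted
    regression. Includes individual-level mother-child duo cohort
    models with covariate adjustment and cross-cohort fixed-effects
    pooling, and a transmission-model simulator of mother-child duo
    cohorts and GWAS-style summary statistics so the full pipeline is
    testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    ggplot2,
    withr,
    optparse
Config/testthat/edition: 3
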