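---
title: "Partitioning maternal and fetal genetic effects on birth weight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning maternal and fetal genetic effects on birth weight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Alleles that predispose to higher adult adiposity might already act in
fetal life and raise birth weight. Testing this from GWAS summary
statistics faces a structural confounder: a mother shares half her alleles
with her child, and maternal adiposity-related genotypes can shape the
intrauterine environment. A raw GWAS of one's *own* birth weight therefore
mixes the direct fetal effect with half the maternal one. duogenie
implements the summary-statistics workflow that separates the two and asks
whether fetal genetic predisposition to adult adiposity — indexed by an
instrument set of independent SNPs — raises birth weight, and whether the
per-SNP effects are *proportional* to the SNPs' adult-trait effects.

## The weighted-linear-model (WLM) partition

Write $\beta_F$ for the direct fetal per-allele effect on birth weight and
$\beta_M$ for the maternal per-allele effect acting through the
intrauterine environment. Because the child carries, in expectation, half
of the maternal alleles,

$$E[\hat\beta_{\text{own}}] = \beta_F + \tfrac12\beta_M, \qquad
  E[\hat\beta_{\text{off}}] = \beta_M + \tfrac12\beta_F,$$

where $\hat\beta_{\text{own}}$ comes from a GWAS of own birth weight and
$\hat\beta_{\text{off}}$ from a GWAS of offspring birth weight on maternal
genotype. Inverting the $2\times 2$ system gives the estimators used by
`partition_effects()`:

$$\hat\beta_F = \tfrac{4\hat\beta_{\text{own}} - 2\hat\beta_{\text{off}}}{3},
\qquad
\hat\beta_M = \tfrac{4\hat\beta_{\text{off}} - 2\hat\beta_{\text{own}}}{3},$$

with $\mathrm{var}(\hat\beta_F) = (16 v_{\text{own}} + 4 v_{\text{off}} -
16c)/9$, where $c$ is the sampling covariance of the two inputs. The
default $c = 0$ is correct when the two GWAS come from non-overlapping
samples. This matters more than it looks: if both regressions are run in
the *same* mother–child sample, the shared residual and the dosage
correlation of 0.5 induce $c > 0$, the default standard error is too
large, and confidence intervals over-cover. `duo_summary_stats()`
therefore accepts a second cohort for the offspring-side GWAS, and all
recovery simulations in the test-suite use disjoint cohorts — mirroring
the mostly non-overlapping participant subsets behind real own/offspring
birth-weight GWAS. Users with overlapping samples should pass a positive
`cov_policy` to `partition_table()`.

The exact multi-subsample weighting schemes used by some published
maternal-adjusted GWAS (separate own-only, offspring-only and both-report
subsets) are not reproduced here; the two-input solver is the documented
default, and `ivw_combine()` provides an inverse-variance combination when
users bring per-subset estimates. Simulation recovery (unbiasedness,
nominal coverage) is the arbiter of correctness for this design.

## Harmonization

Summary statistics report effects relative to an arbitrary allele and
strand. `harmonize_record()` aligns the outcome effect to the exposure's
effect allele by comparing allele labels directly, after an
effect/other swap, after base complementation, and after both; a swap
negates the outcome beta and reflects its allele frequency. Palindromic
SNPs (A/T, C/G) carry no usable label information — the complement of a
swap is indistinguishable from the original — so they are oriented purely
by allele frequency. Frequency orientation is attempted only when both
minor-allele frequencies are at most `palindrome_freq_limit` (default
0.42, the conventional ambiguity window in two-sample harmonization);
otherwise the SNP is dropped, and `palindromic_action = "drop"` disables
frequency alignment entirely, since published pipelines differ on this
point. A palindromic SNP with a missing frequency is a loud error, never a
guess. Instruments reported on the adiposity-*lowering* allele are flipped
so pooled effects read "per adiposity-raising allele".

Instrument QC (`filter_instruments()`) removes explicitly excluded
variants and, for any supplied pair with LD $r^2$ above the limit, the
member with the larger exposure p-value — a deterministic tie-break that
is logged so users can override it by pre-specifying the exclusion.
LD $r^2$ is computed from user-supplied dosage vectors only
(`pairwise_ld_r2()`); no reference-panel lookup is attempted.

## Pooling and heterogeneity

`pool_fixed()` uses inverse-variance weights $w_i = 1/se_i^2$;
`pool_random()` is the DerSimonian–Laird estimator,
$\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i)\}$, with
re-weights $1/(se_i^2 + \tau^2)$. DerSimonian–Laird is the field default
when a method is named only "random effects meta-analysis"; confidence
intervals use the normal 1.96 multiplier rather than a t quantile (the
choice is immaterial at $k \ge 14$ and is stated here because it is
otherwise invisible). $I^2 = \max\{0, (Q-(k-1))/Q\}\cdot 100$. Results in
SD units are rescaled to grams by `sd_to_grams()` with 484 g per SD of
birth weight, the average SD across large birth-weight study collections.
No multiple-testing correction is applied anywhere; outputs are
per-question estimates with their own intervals.

## Dose–response proportionality

`fit_weighted_slope()` regresses per-SNP outcome effects on per-SNP
exposure effects with an intercept and weights $1/se_i^2$ on the outcome
side. The phrase "weighted by the inverse of the standard error" is
ambiguous between $1/se$ and $1/se^2$; the package defaults to $1/se^2$
(the transform-both-sides reading, equivalent to generalized least
squares under the outcome's sampling variance) and exposes
`weight_power = 1` for sensitivity. Variance explained is reported both as
the weighted $R^2$ and as the adjusted value
$1 - (1-R^2)(k-1)/(k-2)$; the adjusted form can be negative, which is the
expected behaviour when effects are not proportional, so small negative
printed values are informative rather than pathological. The slope
p-value uses a t reference with $k-2$ degrees of freedom, the exact
distribution under the weighted normal model.

## Individual-level cohort stage

For mother–child duo cohorts, outcomes are z-scored within each cohort
(`standardize_outcomes()`) so per-allele effects are comparable across
cohorts that measured a trait differently; the ponderal index is derived
first as weight(kg)/length(m)$^3$. Each SNP is then fit by least squares
of the standardized outcome on child dosage, adjusting for maternal
dosage, child sex and gestational age (`fit_snp_model()`); maternal
adjustment is what removes the intrauterine half-effect, while sex and
gestational age are precision covariates. Missing data are handled by
listwise deletion with counts reported; constant precision covariates
(e.g. sex in a single-sex subset) are dropped, whereas a constant dosage
is a hard error. Per-SNP estimates are pooled across cohorts by
*fixed-effects* meta-analysis with Cochran's Q and $I^2$
(`meta_across_cohorts()`) — cross-cohort pooling happens before any
across-SNP random-effects pooling, matching the declared analysis order of
multi-cohort perinatal studies. Cord-blood analytes are analysed on the
natural scale by default, with a `log_transform` argument because both
conventions exist. Record-level exclusions (`apply_exclusions()`) mirror
birth-record quality practice: births under 2200 g (a proxy for
excluding preterm births where gestational age is unrecorded), multiple
births, and duplicate birth-weight reports differing by more than 500 g.

## What the simulator emulates — and what it does not

`simulate_duo_cohort()` draws maternal genotypes Binomial(2, f),
transmits one uniformly chosen maternal allele and adds an independent
paternal allele — giving mother–child dosage correlation 0.5 and
Hardy–Weinberg children — then builds birth weight additively from
configured fetal and maternal per-SNP effects plus Gaussian noise.
Defaults emulate a metabolically-favorable-adiposity-style study: 14
independent SNPs with adult-trait effects spread over 0.02–0.08 SD,
fetal effects exactly proportional with slope 0.124 so the mean
per-allele effect is about 3 g on the 484 g/SD scale, no maternal
effects, frequencies spread over 0.15–0.85, and GWAS cohorts of 50 000
duos. Secondary outcomes share a configurable fraction of the genetic
signal. The simulator deliberately omits LD between SNPs (instrument sets
are LD-pruned by construction), assortative mating, paternal effects,
parent-of-origin effects, genotype–covariate correlation and
non-Gaussian outcome tails. Passing tests therefore demonstrate the
estimators' statistical correctness under the assumed transmission model,
not robustness to those real-data complications.

## Problem sizes and numerical choices

The test-suite's simulation sizes are chosen so the whole suite runs in
about a minute on one core while keeping Monte-Carlo error well inside
the asserted tolerances: 200 replicate studies of 50 000 duos for WLM
recovery and coverage, 100 000 duos for transmission and bias checks,
1000 random instances for the meta-analysis and weighted-regression
oracle equivalences, and 1000 null replicates for the adjusted-$R^2$
calibration. Pipeline outputs are written with 6 significant digits;
internal computation keeps full double precision. All randomness is
seeded; identical configuration and seed reproduce cohorts bit for bit.

## Interfaces

The package's functions are the primary interface; `run_pipeline()`
orchestrates the stages from a single configuration (R list or YAML) and
writes stage TSVs plus a JSON manifest of digests, counts and seeds, and
`inst/cli/duogenie.R` is a thin Rscript wrapper over the same functions
for shell use. `scripts/acceptance.R` (repository root) recomputes the
headline quantities from scratch on the synthetic study conditions.

## Known limitations

Coordinates are treated as opaque keys (no genome-build liftover);
indels and multi-allelic variants are rejected rather than harmonized;
no LD-aware instrument selection or reference-panel proxy lookup is
provided; the random-effects CI does not use the Hartung–Knapp
adjustment; and real cohort data access, imputation and ancestry control
are out of scope — the individual-level stage expects analysis-ready duo
tables.
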