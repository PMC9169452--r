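# Transmission-model simulator of mother-child duo cohorts.
#
# Generative model, per SNP with effect-allele frequency f:
#   maternal dosage  M ~ Binomial(2, f)
#   transmitted allele ~ Bernoulli(M/2)   (one maternal allele, uniformly)
#   paternal allele    ~ Bernoulli(f)     (independent, population frequency)
#   child dosage     C = transmitted + paternal
# which gives cor(C, M) = 0.5 and Hardy-Weinberg genotype frequencies in
# the children. Birth weight in SD units is
#   BW = sum_j (bF_j C_j + bM_j M_j) + Normal(0, noise_sd)
# and in grams BW * sd_grams. The adult adiposity trait is not simulated at
# the individual level; its per-SNP effects (gamma_j) are part of the
# configuration, linked to the fetal effects by bF_j =
# proportionality_slope * gamma_j + Normal(0, fetal_effect_noise_sd), so
# proportionality is a generating parameter the dose-response stage can be
# tested against.

#' Configuration for the mother-child duo generator
#'
#' Defaults emulate a metabolically-favorable-adiposity-style instrument
#' set: 14 independent biallelic SNPs, adult-trait effects spread over
#' 0.02-0.08 SD, fetal birth-weight effects proportional to them with a
#' slope such that the mean per-allele fetal effect is about 3 g on the
#' 484 g/SD scale, no maternal effects, and unit residual SD for a
#' standardized birth weight.
#'
#' @param n_individuals Duos per cohort.
#' @param n_snps Number of independent SNPs.
#' @param allele_freqs Effect-allele frequencies in (0, 1); recycled.
#' @param adult_trait_betas Per-SNP adult-trait effects (the exposure
#'   weights), effect allele = raising allele.
#' @param adult_trait_ses Standard errors attached to the adult-trait
#'   effects when an instrument table is emitted.
#' @param proportionality_slope Slope linking fetal birth-weight effects to
#'   adult-trait effects (SD birth weight per unit adult trait).
#' @param fetal_effect_noise_sd SD of per-SNP deviations from exact
#'   proportionality (0 = exactly proportional).
#' @param beta_fetal Optional explicit per-SNP fetal effects (SD units);
#'   overrides the proportional construction.
#' @param beta_maternal Per-SNP maternal effects (SD units); recycled.
#' @param noise_sd Residual SD of birth weight in SD units (> 0).
#' @param sd_grams Grams per SD of birth weight.
#' @param effect_share Named vector scaling the genetic effects on the
#'   secondary outcomes (birth length, head circumference, skinfolds, cord
#'   insulin) relative to birth weight.
#' @param multiple_birth_rate Probability a duo is flagged as a multiple
#'   birth.
#' @param report_error_sd SD (grams) of the discrepancy between the two
#'   birth-weight reports carried in `birth_weight_report2_g`.
#' @param palindromic_fraction Fraction of SNPs given strand-ambiguous
#'   (A/T or C/G) allele pairs.
#' @param cohort Cohort label.
#' @param seed RNG seed making the cohort fully reproducible.
#' @return Validated `duo_config` list.
#' @export
duo_config <- function(n_individuals = 10000,
                       n_snps = 14,
                       allele_freqs = seq(0.15, 0.85, length.out = n_snps),
                       adult_trait_betas = seq(0.02, 0.08,
                                               length.out = n_snps),
                       adult_trait_ses = 0.004,
                       proportionality_slope = 0.124,
                       fetal_effect_noise_sd = 0,
                       beta_fetal = NULL,
                       beta_maternal = 0,
                       noise_sd = 1,
                       sd_grams = 484,
                       effect_share = c(birth_length_cm = 0.5,
                                        head_circumference_cm = 0.3,
                                        sum_skinfolds_mm = 0.4,
                                        cord_insulin_pmol_l = 0.2),
                       multiple_birth_rate = 0,
                       report_error_sd = 0,
                       palindromic_fraction = 0,
                       cohort = "synthetic",
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    allele_freqs = rep_len(allele_freqs, n_snps),
    adult_trait_betas = rep_len(adult_trait_betas, n_snps),
    adult_trait_ses = rep_len(adult_trait_ses, n_snps),
    proportionality_slope = proportionality_slope,
    fetal_effect_noise_sd = fetal_effect_noise_sd,
    beta_fetal = if (is.null(beta_fetal)) NULL else
      rep_len(beta_fetal, n_snps),
    beta_maternal = rep_len(beta_maternal, n_snps),
    noise_sd = noise_sd, sd_grams = sd_grams,
    effect_share = effect_share,
    multiple_birth_rate = multiple_birth_rate,
    report_error_sd = report_error_sd,
    palindromic_fraction = palindromic_fraction,
    cohort = cohort, seed = as.integer(seed)
  )
  if (cfg$n_individuals < 1 || cfg$n_snps < 1)
    stop("config error: n_individuals and n_snps must be positive",
         call. = FALSE)
  if (any(cfg$allele_freqs <= 0) || any(cfg$allele_freqs >= 1))
    stop("config error: allele frequencies must lie strictly in (0, 1)",
         call. = FALSE)
  if (cfg$noise_sd <= 0 || cfg$sd_grams <= 0)
    stop("config error: noise_sd and sd_grams must be > 0", call. = FALSE)
  if (cfg$multiple_birth_rate < 0 || cfg$multiple_birth_rate > 1)
    stop("config error: multiple_birth_rate must lie in [0, 1]",
         call. = FALSE)
  class(cfg) <- "duo_config"
  cfg
}

# per-SNP fetal effects implied by the config
.config_beta_fetal <- function(config, rng_offset = 1000003L) {
  if (!is.null(config$beta_fetal)) return(config$beta_fetal)
  b <- config$proportionality_slope * config$adult_trait_betas
  if (config$fetal_effect_noise_sd > 0) {
    # deviations drawn from a seed-derived stream so cohorts sharing a
    # config share the same true per-SNP effects
    b <- b + withr_seed_rnorm(config$seed + rng_offset, config$n_snps,
                              sd = config$fetal_effect_noise_sd)
  }
  b
}

# rnorm under a local seed without disturbing the caller's RNG state
withr_seed_rnorm <- function(seed, n, sd = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rnorm(n, sd = sd)
}

# deterministic non-palindromic / palindromic allele assignment
.config_alleles <- function(config) {
  n <- config$n_snps
  n_pal <- round(config$palindromic_fraction * n)
  nonpal <- rbind(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"),
                  c("A", "C"), c("G", "T"))
  pal <- rbind(c("A", "T"), c("C", "G"))
  ea <- oa <- character(n)
  for (i in seq_len(n)) {
    src <- if (i <= n_pal) pal[(i - 1L) %% nrow(pal) + 1L, ]
           else nonpal[(i - 1L) %% nrow(nonpal) + 1L, ]
    ea[i] <- src[1]; oa[i] <- src[2]
  }
  list(ea = ea, oa = oa)
}

#' Simulate one mother-child duo cohort
#'
#' Draws maternal genotypes at the configured frequencies, transmits one
#' uniformly chosen maternal allele per duo and adds an independent paternal
#' allele, then generates birth weight and the secondary perinatal outcomes
#' under the additive fetal + maternal effect model. Sex and gestational age
#' are generated independent of genotype (precision covariates, not
#' confounders). Fully reproducible from `config$seed`.
#'
#' @param config A [duo_config()].
#' @return A `duo_cohort` list: `cohort`, `snp_ids`, `maternal_dosage` and
#'   `child_dosage` (n x SNP integer matrices), `outcomes` (data.frame with
#'   `birth_weight_sd`, `birth_weight_g`, `birth_weight_report2_g`,
#'   `birth_length_cm`, `head_circumference_cm`, `sum_skinfolds_mm`,
#'   `cord_insulin_pmol_l`, `multiple_birth`), `sex` (0/1),
#'   `gestational_age` (weeks), `config`, `seed`.
#' @export
simulate_duo_cohort <- function(config) {
  stopifnot(inherits(config, "duo_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_snps
  f <- config$allele_freqs

  maternal <- sapply(f, function(p) rbinom(n, 2L, p))
  transmitted <- matrix(rbinom(n * m, 1L, as.vector(maternal) / 2),
                        nrow = n)
  paternal <- sapply(f, function(p) rbinom(n, 1L, p))
  child <- transmitted + paternal
  # ids depend only on the SNP index so cohorts simulated under different
  # seeds but one study design stay joinable
  snp_ids <- sprintf("rs%07d", seq_len(m) * 101)
  colnames(maternal) <- colnames(child) <- snp_ids

  bF <- .config_beta_fetal(config)
  bM <- config$beta_maternal
  genetic <- as.vector(child %*% bF + maternal %*% bM)
  bw_sd <- genetic + rnorm(n, sd = config$noise_sd)

  sex <- rbinom(n, 1L, 0.5)
  gest <- rnorm(n, mean = 39.5, sd = 1.3)

  share <- config$effect_share
  sec <- function(name, mean, sd_units) {
    s <- if (name %in% names(share)) share[[name]] else 0
    mean + sd_units * (s * genetic + rnorm(n, sd = sqrt(max(0, 1 - s^2))))
  }
  bw_g <- 3500 + config$sd_grams * bw_sd  # centred at a realistic 3500 g
  outcomes <- data.frame(
    birth_weight_sd = bw_sd,
    birth_weight_g = bw_g,
    birth_weight_report2_g = bw_g + if (config$report_error_sd > 0)
      rnorm(n, sd = config$report_error_sd) else 0,
    birth_length_cm = sec("birth_length_cm", 50, 2.2),
    head_circumference_cm = sec("head_circumference_cm", 34.5, 1.4),
    sum_skinfolds_mm = sec("sum_skinfolds_mm", 9.5, 2.0),
    cord_insulin_pmol_l = sec("cord_insulin_pmol_l", 40, 18),
    multiple_birth = rbinom(n, 1L, config$multiple_birth_rate) == 1L
  )

  structure(list(
    cohort = config$cohort, snp_ids = snp_ids,
    maternal_dosage = maternal, child_dosage = child,
    outcomes = outcomes, sex = sex, gestational_age = gest,
    config = config, seed = config$seed
  ), class = "duo_cohort")
}

#' @export
print.duo_cohort <- function(x, ...) {
  cat(sprintf("duo_cohort '%s': %d mother-child pairs, %d SNPs, seed %d\n",
              x$cohort, nrow(x$child_dosage), length(x$snp_ids), x$seed))
  invisible(x)
}

#' Flatten a duo cohort to one individual-level data.frame
#'
#' Child and maternal dosages become columns `child_<rsid>` and
#' `mother_<rsid>`, matching the tab-delimited cohort interchange format.
#'
#' @param x A `duo_cohort`.
#' @param ... Unused.
#' @return data.frame with id, sex, gestational age, outcomes and dosages.
#' @export
as.data.frame.duo_cohort <- function(x, ...) {
  child <- as.data.frame(x$child_dosage)
  names(child) <- paste0("child_", x$snp_ids)
  mother <- as.data.frame(x$maternal_dosage)
  names(mother) <- paste0("mother_", x$snp_ids)
  cbind(data.frame(id = seq_len(nrow(child)), cohort = x$cohort,
                   sex = x$sex, gestational_age = x$gestational_age,
                   stringsAsFactors = FALSE),
        x$outcomes, child, mother)
}

#' Instrument table implied by a generator configuration
#'
#' Emits the per-SNP adult-trait effects of the configuration as an
#' [instrument_set()], with the raising allele as effect allele — the
#' synthetic counterpart of a published adult-adiposity instrument list.
#'
#' @param config A [duo_config()].
#' @param name Label for the set.
#' @return An `instrument_set`.
#' @export
instrument_sumstats <- function(config, name = "synthetic-adiposity") {
  al <- .config_alleles(config)
  snp_ids <- sprintf("rs%07d", seq_len(config$n_snps) * 101)
  beta <- config$adult_trait_betas
  se <- config$adult_trait_ses
  instrument_set(data.frame(
    snp_id = snp_ids, chrom = as.character(seq_len(config$n_snps)),
    pos = seq_len(config$n_snps) * 1e6,
    effect_allele = al$ea, other_allele = al$oa,
    eaf = config$allele_freqs, beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)), n = 450000,
    stringsAsFactors = FALSE
  ), name = name, trait_units = "SD adult trait")
}

# closed-form simple regression of y on each dosage column
.marginal_gwas <- function(dosage, y, config, n_col) {
  n <- length(y)
  out <- vector("list", ncol(dosage))
  al <- .config_alleles(config)
  for (j in seq_len(ncol(dosage))) {
    g <- dosage[, j]
    vx <- var(g)
    if (vx == 0) {
      warning("monomorphic SNP ", colnames(dosage)[j], " dropped")
      next
    }
    beta <- cov(g, y) / vx
    resid <- y - mean(y) - beta * (g - mean(g))
    se <- sqrt(sum(resid^2) / (n - 2) / ((n - 1) * vx))
    out[[j]] <- data.frame(
      snp_id = colnames(dosage)[j], chrom = as.character(j), pos = j * 1e6,
      effect_allele = al$ea[j], other_allele = al$oa[j],
      eaf = mean(g) / 2, beta = beta, se = se,
      pval = 2 * pt(-abs(beta / se), df = n - 2), n = n_col,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' GWAS-style summary statistics from duo cohorts
#'
#' Per SNP, regresses the child's outcome on the child dosage (the
#' "own birth weight" GWAS) and, in a second cohort, on the maternal dosage
#' (the "offspring birth weight" GWAS of maternal genotype). Supplying two
#' independently simulated cohorts mirrors non-overlapping GWAS samples, for
#' which the weighted-linear-model default of zero covariance between the
#' two estimates holds; running both regressions in one cohort induces a
#' positive covariance that must then be passed to [partition_table()].
#'
#' @param cohort `duo_cohort` providing the own-outcome GWAS.
#' @param off_cohort `duo_cohort` providing the maternal-genotype GWAS;
#'   defaults to `cohort` (overlapping-sample setting).
#' @param outcome Name of the outcome column (default `birth_weight_sd`).
#' @return List with canonical summary-statistics data.frames `own` and
#'   `offspring`.
#' @export
duo_summary_stats <- function(cohort, off_cohort = cohort,
                              outcome = "birth_weight_sd") {
  if (nrow(cohort$child_dosage) < 100 ||
      nrow(off_cohort$child_dosage) < 100)
    stop("duo_summary_stats needs cohorts of at least 100 duos",
         call. = FALSE)
  own <- .marginal_gwas(cohort$child_dosage, cohort$outcomes[[outcome]],
                        cohort$config, nrow(cohort$child_dosage))
  off <- .marginal_gwas(off_cohort$maternal_dosage,
                        off_cohort$outcomes[[outcome]],
                        off_cohort$config, nrow(off_cohort$child_dosage))
  list(own = own, offspring = off)
}
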