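# Weighted-linear-model (WLM) partition of birth-weight GWAS effects.
#
# A child carries, on average, half of its mother's alleles. A GWAS of
# one's own birth weight therefore estimates beta_own = b_F + b_M/2, and a
# GWAS of offspring birth weight on maternal genotype estimates
# beta_off = b_M + b_F/2, where b_F is the direct fetal per-allele effect
# and b_M the maternal (intrauterine) one. Inverting this 2x2 system gives
#   b_F = (4 beta_own - 2 beta_off) / 3
#   b_M = (4 beta_off - 2 beta_own) / 3
# with var(b_F) = (16 var_own + 4 var_off - 16 cov) / 9 (and symmetrically
# for b_M), where cov is the sampling covariance of the two input estimates
# (0 for non-overlapping GWAS samples).

#' Partition own- and offspring-birth-weight effects into fetal and maternal
#' components
#'
#' @param beta_own Per-allele effect from the GWAS of one's own birth
#'   weight. Vectorized over SNPs.
#' @param se_own Its standard error (> 0).
#' @param beta_off Per-allele effect from the maternal GWAS of offspring
#'   birth weight, for the same effect allele.
#' @param se_off Its standard error (> 0).
#' @param cov Sampling covariance between the two input estimates; 0 for
#'   independent samples. Recycled over SNPs.
#' @param snp_id Optional SNP identifiers carried into the output.
#' @return Data.frame with `snp_id`, `beta_fetal`, `se_fetal`,
#'   `beta_maternal`, `se_maternal`, `cov_inputs`.
#' @examples
#' # a purely fetal effect b shows up as beta_own = b, beta_off = b/2
#' partition_effects(0.10, 0.01, 0.05, 0.01)
#' @export
partition_effects <- function(beta_own, se_own, beta_off, se_off, cov = 0,
                              snp_id = NULL) {
  if (any(se_own <= 0) || any(se_off <= 0))
    stop("standard errors must be > 0", call. = FALSE)
  n <- max(length(beta_own), length(beta_off))
  cov <- rep_len(cov, n)
  beta_fetal    <- (4 * beta_own - 2 * beta_off) / 3
  beta_maternal <- (4 * beta_off - 2 * beta_own) / 3
  var_fetal    <- (16 * se_own^2 + 4 * se_off^2 - 16 * cov) / 9
  var_maternal <- (16 * se_off^2 + 4 * se_own^2 - 16 * cov) / 9
  if (any(var_fetal <= 0) || any(var_maternal <= 0))
    stop("variance propagation error: input covariance too large for the ",
         "given standard errors", call. = FALSE)
  data.frame(
    snp_id = if (is.null(snp_id)) rep(NA_character_, n) else snp_id,
    beta_fetal = beta_fetal, se_fetal = sqrt(var_fetal),
    beta_maternal = beta_maternal, se_maternal = sqrt(var_maternal),
    cov_inputs = cov, stringsAsFactors = FALSE
  )
}

#' WLM-partition two summary-statistics tables SNP by SNP
#'
#' Joins the own-birth-weight and offspring-birth-weight tables on `snp_id`
#' and applies [partition_effects()] per SNP. Both tables must already refer
#' to the same effect allele per SNP — this is asserted, and a mismatch is
#' an error directing the caller to harmonize first, never a silent flip.
#'
#' @param own Canonical summary-statistics data.frame for own birth weight.
#' @param off Canonical summary-statistics data.frame for offspring birth
#'   weight (maternal genotype GWAS).
#' @param cov_policy Per-SNP input covariance: a single number (default 0,
#'   non-overlapping samples) or a function of the merged table returning a
#'   numeric vector.
#' @return List with `estimates` (a data.frame of WLM estimates that also
#'   carries the allele columns, so the fetal effects can be consumed
#'   downstream exactly like a summary-statistics table via
#'   [wlm_to_sumstats()]) and `missing` (SNP ids present in only one input).
#' @export
partition_table <- function(own, off, cov_policy = 0) {
  common <- intersect(own$snp_id, off$snp_id)
  missing <- c(setdiff(own$snp_id, off$snp_id),
               setdiff(off$snp_id, own$snp_id))
  if (!length(common))
    return(list(estimates = NULL, missing = missing))
  a <- as.data.frame(own)[match(common, own$snp_id), , drop = FALSE]
  b <- as.data.frame(off)[match(common, off$snp_id), , drop = FALSE]
  mismatch <- a$effect_allele != b$effect_allele |
    a$other_allele != b$other_allele
  if (any(mismatch))
    stop("harmonization required: own and offspring records disagree on ",
         "alleles for SNP(s) ", paste(common[mismatch], collapse = ", "),
         call. = FALSE)
  cov <- if (is.function(cov_policy)) cov_policy(a) else cov_policy
  est <- partition_effects(a$beta, a$se, b$beta, b$se, cov = cov,
                           snp_id = common)
  est$chrom <- a$chrom; est$pos <- a$pos
  est$effect_allele <- a$effect_allele; est$other_allele <- a$other_allele
  est$eaf <- a$eaf
  est$n <- pmin(a$n, b$n)
  rownames(est) <- NULL
  list(estimates = est, missing = missing)
}

#' Convert WLM estimates to a fetal-effect summary-statistics table
#'
#' Re-expresses the maternal-adjusted fetal effects as a canonical
#' summary-statistics data.frame, so downstream stages consume WLM output
#' and pre-adjusted public downloads identically.
#'
#' @param estimates The `estimates` element of [partition_table()].
#' @param component `"fetal"` (default) or `"maternal"`.
#' @return Canonical summary-statistics data.frame (p-values from the
#'   two-sided normal z-test).
#' @export
wlm_to_sumstats <- function(estimates, component = c("fetal", "maternal")) {
  component <- match.arg(component)
  beta <- estimates[[paste0("beta_", component)]]
  se <- estimates[[paste0("se_", component)]]
  data.frame(
    snp_id = estimates$snp_id, chrom = estimates$chrom, pos = estimates$pos,
    effect_allele = estimates$effect_allele,
    other_allele = estimates$other_allele, eaf = estimates$eaf,
    beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)),
    n = estimates$n, stringsAsFactors = FALSE
  )
}

#' Inverse-variance combination of sub-sample estimates
#'
#' When the fetal (or maternal) effect has been estimated separately in
#' several non-overlapping participant subsets, the sub-estimates are
#' combined with inverse-variance weights — the same fixed-effect rule used
#' in [pool_fixed()], exposed here for per-SNP use.
#'
#' @param betas,ses Numeric vectors of sub-sample estimates and their
#'   standard errors.
#' @return List with `beta`, `se` and the normalized `weights`.
#' @export
ivw_combine <- function(betas, ses) {
  if (any(ses <= 0)) stop("standard errors must be > 0", call. = FALSE)
  w <- 1 / ses^2
  list(beta = sum(w * betas) / sum(w), se = sqrt(1 / sum(w)),
       weights = w / sum(w))
}
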