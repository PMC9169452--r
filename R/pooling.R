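# Per-allele meta-analysis across an instrument set.
#
# Pooling k per-SNP effect estimates with inverse-variance weights gives the
# average per-allele effect of the instrument set. Fixed-effect weights are
# w_i = 1/se_i^2; the DerSimonian-Laird random-effects model adds a
# between-SNP variance tau^2 estimated from Cochran's Q and re-weights with
# w*_i = 1/(se_i^2 + tau^2). I^2 expresses the share of total variation
# attributable to heterogeneity.

.new_pooled <- function(estimate, se, k, q_stat, tau2, i2, model) {
  structure(list(
    estimate = estimate, se = se,
    ci_low = estimate - qnorm(0.975) * se,
    ci_high = estimate + qnorm(0.975) * se,
    pval = 2 * pnorm(-abs(estimate / se)),
    k = k, q_stat = q_stat, q_df = k - 1L,
    tau2 = tau2, i2 = i2, model = model
  ), class = "pooled_effect")
}

.check_pool_input <- function(betas, ses) {
  if (length(betas) != length(ses))
    stop("betas and ses differ in length", call. = FALSE)
  if (length(betas) < 2)
    stop("insufficient input: pooling needs at least 2 estimates",
         call. = FALSE)
  if (any(is.na(betas)) || any(is.na(ses)))
    stop("missing values in betas/ses", call. = FALSE)
  if (any(ses <= 0))
    stop("validation error: all standard errors must be > 0", call. = FALSE)
}

#' Fixed-effect (inverse-variance) meta-analysis
#'
#' @param betas Per-unit effect estimates (one per SNP, or per cohort).
#' @param ses Their standard errors (> 0).
#' @return A `pooled_effect`: `estimate`, `se`, normal 95% `ci_low`/
#'   `ci_high`, two-sided `pval`, `k`, Cochran's `q_stat` with `q_df = k-1`,
#'   `tau2` (0 under the fixed-effect model), `i2` (percent) and `model`.
#' @examples
#' pool_fixed(c(0.1, 0.3), c(0.1, 0.1))  # 0.2 +/- 0.0707, Q = 2
#' @export
pool_fixed <- function(betas, ses) {
  .check_pool_input(betas, ses)
  w <- 1 / ses^2
  est <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - est)^2)
  k <- length(betas)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  .new_pooled(est, sqrt(1 / sum(w)), k, q, tau2 = 0, i2 = i2,
              model = "fixed")
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Estimates the between-SNP variance as
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w`, then pools with `w* = 1/(se^2 + tau2)`.
#' When the estimates are homogeneous (`Q <= k-1`), `tau2 = 0` and the
#' result coincides with [pool_fixed()].
#'
#' @inheritParams pool_fixed
#' @return A `pooled_effect` (see [pool_fixed()]) with `model = "random"`.
#' @examples
#' pool_random(c(0.1, 0.2, 0.3), c(0.05, 0.05, 0.05))
#' @export
pool_random <- function(betas, ses) {
  .check_pool_input(betas, ses)
  w <- 1 / ses^2
  k <- length(betas)
  fe <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - fe)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  ws <- 1 / (ses^2 + tau2)
  est <- sum(ws * betas) / sum(ws)
  .new_pooled(est, sqrt(1 / sum(ws)), k, q, tau2 = tau2, i2 = i2,
              model = "random")
}

#' Rescale an effect from birth-weight SD units to grams
#'
#' Multiplies the point estimate, standard error and confidence bounds by
#' the population SD of birth weight in grams (484 g, the average across the
#' contributing birth-weight studies); p-values, Q and I^2 are scale-free and
#' unchanged, while `tau2` rescales by `sd_grams^2`.
#'
#' @param effect A `pooled_effect`, or a list/data.frame with `beta` and
#'   `se` (and optionally `ci_low`, `ci_high`) components.
#' @param sd_grams Grams per SD of birth weight (> 0); default 484.
#' @return Object of the same shape with all location/scale fields in grams.
#' @export
sd_to_grams <- function(effect, sd_grams = 484) {
  if (!is.numeric(sd_grams) || length(sd_grams) != 1 || sd_grams <= 0)
    stop("validation error: sd_grams must be a single positive number",
         call. = FALSE)
  if (inherits(effect, "pooled_effect")) {
    effect$estimate <- effect$estimate * sd_grams
    effect$se <- effect$se * sd_grams
    effect$ci_low <- effect$ci_low * sd_grams
    effect$ci_high <- effect$ci_high * sd_grams
    effect$tau2 <- effect$tau2 * sd_grams^2
    return(effect)
  }
  for (f in c("beta", "se", "ci_low", "ci_high"))
    if (!is.null(effect[[f]])) effect[[f]] <- effect[[f]] * sd_grams
  effect
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf("%s-effects meta-analysis of %d SNPs\n", x$model, x$k))
  cat(sprintf("  per-allele effect: %.4g (95%% CI %.4g to %.4g), p = %.4g\n",
              x$estimate, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  heterogeneity: Q = %.4g (df = %d), tau^2 = %.4g, I^2 = %.1f%%\n",
              x$q_stat, x$q_df, x$tau2, x$i2))
  invisible(x)
}

#' @export
as.data.frame.pooled_effect <- function(x, ...) {
  data.frame(estimate = x$estimate, se = x$se, ci_low = x$ci_low,
             ci_high = x$ci_high, pval = x$pval, k = x$k,
             q_stat = x$q_stat, q_df = x$q_df, tau2 = x$tau2, i2 = x$i2,
             model = x$model, stringsAsFactors = FALSE)
}
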