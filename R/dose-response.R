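# Dose-response proportionality of SNP effects.
#
# If fetal alleles raise birth weight through the same biology that raises
# the adult trait, SNPs with larger adult-trait effects should show larger
# birth-weight effects. This is tested with a weighted linear regression of
# the per-SNP outcome effects on the per-SNP exposure effects (intercept
# included), weighting each SNP by the precision of its outcome estimate.

#' SE-weighted dose-response regression of SNP effects
#'
#' Weighted least squares of `outcome_beta` on `exposure_beta` with an
#' intercept and weights `1/outcome_se^weight_power`. The weighted R-squared
#' uses weighted residual and total sums of squares about the weighted mean;
#' the adjusted value `1 - (1 - R2) (k - 1)/(k - 2)` can be negative when
#' the slope explains less than one parameter's worth of variance — the
#' expected outcome when effects are not proportional. The slope p-value is
#' two-sided from a t reference with `k - 2` degrees of freedom.
#'
#' @param exposure_beta Per-SNP effects on the adult trait (x-axis).
#' @param outcome_beta Per-SNP effects on the outcome, aligned to the same
#'   effect allele (y-axis).
#' @param outcome_se Standard errors of the outcome effects (> 0).
#' @param weight_power 2 (default) weights by inverse variance; 1 weights by
#'   inverse SE, for sensitivity.
#' @return A `dose_response_fit`: `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `r2`, `adj_r2`, `pval_slope`, `k`, `weight_power`.
#' @examples
#' fit_weighted_slope(c(0, 1, 2), c(0, 1, 1), c(1, 1, 1))
#' @export
fit_weighted_slope <- function(exposure_beta, outcome_beta, outcome_se,
                               weight_power = 2) {
  k <- length(exposure_beta)
  if (k < 3)
    stop("insufficient input: dose-response fit needs at least 3 SNPs",
         call. = FALSE)
  if (length(outcome_beta) != k || length(outcome_se) != k)
    stop("input vectors differ in length", call. = FALSE)
  if (any(outcome_se <= 0))
    stop("validation error: all outcome standard errors must be > 0",
         call. = FALSE)
  if (var(exposure_beta) == 0)
    stop("degenerate design: exposure betas have zero variance",
         call. = FALSE)
  w <- 1 / outcome_se^weight_power
  fit <- lm(outcome_beta ~ exposure_beta, weights = w)
  s <- summary(fit)
  structure(list(
    slope = unname(coef(fit)[2]),
    slope_se = s$coefficients[2, 2],
    intercept = unname(coef(fit)[1]),
    intercept_se = s$coefficients[1, 2],
    r2 = s$r.squared,
    adj_r2 = s$adj.r.squared,
    pval_slope = s$coefficients[2, 4],
    k = k, weight_power = weight_power
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("weighted dose-response regression over %d SNPs (weights 1/SE^%g)\n",
              x$k, x$weight_power))
  cat(sprintf("  slope %.4g (SE %.4g), p = %.4g\n",
              x$slope, x$slope_se, x$pval_slope))
  cat(sprintf("  intercept %.4g (SE %.4g)\n", x$intercept, x$intercept_se))
  cat(sprintf("  R^2 = %.4f, adjusted R^2 = %.4f\n", x$r2, x$adj_r2))
  invisible(x)
}

#' @export
as.data.frame.dose_response_fit <- function(x, ...) {
  data.frame(slope = x$slope, slope_se = x$slope_se,
             intercept = x$intercept, intercept_se = x$intercept_se,
             r2 = x$r2, adj_r2 = x$adj_r2, pval_slope = x$pval_slope,
             k = x$k, weight_power = x$weight_power,
             stringsAsFactors = FALSE)
}

#' Scatter plot of SNP outcome effects against exposure effects
#'
#' Renders the per-SNP effects with 95% confidence bars on the outcome axis
#' and the weighted regression line from [fit_weighted_slope()]. Requires
#' ggplot2.
#'
#' @param harmonized Data.frame from [harmonize_pairs()] (rows with
#'   `resolution == "dropped"` are ignored).
#' @param fit Optional pre-computed `dose_response_fit`; refitted when NULL.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(harmonized, fit = NULL,
                               xlab = "SNP effect on adult trait",
                               ylab = "SNP effect on birth weight") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_dose_response requires the ggplot2 package", call. = FALSE)
  d <- harmonized[harmonized$resolution != "dropped", , drop = FALSE]
  if (is.null(fit))
    fit <- fit_weighted_slope(d$aligned_exposure_beta,
                              d$aligned_outcome_beta, d$outcome_se)
  z <- qnorm(0.975)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$aligned_exposure_beta,
                                  y = .data$aligned_outcome_beta)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$aligned_outcome_beta - z * .data$outcome_se,
      ymax = .data$aligned_outcome_beta + z * .data$outcome_se),
      width = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = xlab, y = ylab,
                  subtitle = sprintf("slope %.3g, adj R² %.3f, p %.3g",
                                     fit$slope, fit$adj_r2,
                                     fit$pval_slope)) +
    ggplot2::theme_minimal()
}
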