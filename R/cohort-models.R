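# Individual-level mother-child cohort analyses.
#
# Each cohort is analysed separately: outcomes are z-scored within the
# cohort (so per-allele effects are comparable across cohorts that measured
# the trait differently), each SNP is regressed on the standardized outcome
# with adjustment for maternal dosage, child sex and gestational age, and
# per-SNP results are pooled across cohorts with fixed-effects
# meta-analysis, reporting Cochran's Q and I^2 for between-cohort
# heterogeneity.

.outcome_columns <- function(cohort) {
  num <- vapply(cohort$outcomes, is.numeric, logical(1))
  setdiff(names(cohort$outcomes)[num],
          c("multiple_birth", "birth_weight_report2_g"))
}

#' Standardize cohort outcomes within cohort
#'
#' Replaces each outcome column by its within-cohort z-score computed over
#' non-missing values (missingness preserved). The ponderal index
#' (weight in kg over length in m cubed) is derived first when birth weight
#' and length are available and the column is absent. Cord-blood analytes
#' can be log-transformed before z-scoring.
#'
#' @param cohort A `duo_cohort`.
#' @param outcomes Columns to standardize; defaults to every numeric
#'   outcome.
#' @param log_transform Character vector of outcome columns to
#'   log-transform (natural log) before z-scoring; default none.
#' @return The cohort with z-scored outcome columns.
#' @export
standardize_outcomes <- function(cohort, outcomes = NULL,
                                 log_transform = character()) {
  out <- cohort$outcomes
  if (!"ponderal_index_kg_m3" %in% names(out) &&
      all(c("birth_weight_g", "birth_length_cm") %in% names(out))) {
    out$ponderal_index_kg_m3 <-
      (out$birth_weight_g / 1000) / (out$birth_length_cm / 100)^3
  }
  cohort$outcomes <- out
  if (is.null(outcomes)) outcomes <- .outcome_columns(cohort)
  for (col in outcomes) {
    x <- out[[col]]
    if (col %in% log_transform) x <- log(x)
    ok <- !is.na(x)
    if (sum(ok) < 2 || sd(x[ok]) == 0)
      stop("degenerate outcome: '", col,
           "' has fewer than 2 values or zero variance", call. = FALSE)
    x[ok] <- (x[ok] - mean(x[ok])) / sd(x[ok])
    out[[col]] <- x
  }
  cohort$outcomes <- out
  cohort
}

#' Per-SNP regression of a standardized outcome in one cohort
#'
#' Least-squares fit of the (already standardized) outcome on the child's
#' effect-allele dosage, adjusting for maternal dosage, the child's sex and
#' gestational age. Rows with any missing model variable are excluded
#' listwise and counted. The maternal-dosage adjustment is what removes the
#' intrauterine confounding carried by the mother-child genotype
#' correlation of 0.5.
#'
#' @param cohort A `duo_cohort` (standardize first; the fit does not
#'   re-scale).
#' @param snp_id One of `cohort$snp_ids`.
#' @param outcome Outcome column name.
#' @param adjust_maternal Include the maternal dosage covariate (default
#'   TRUE).
#' @return One-row data.frame (`cohort`, `snp_id`, `outcome`, `beta`, `se`,
#'   `n_used`, `n_dropped`) where `beta` is the child-dosage coefficient.
#' @export
fit_snp_model <- function(cohort, snp_id, outcome = "birth_weight_sd",
                          adjust_maternal = TRUE) {
  j <- match(snp_id, cohort$snp_ids)
  if (is.na(j)) stop("unknown SNP ", snp_id, call. = FALSE)
  d <- data.frame(
    y = cohort$outcomes[[outcome]],
    child = cohort$child_dosage[, j],
    mother = cohort$maternal_dosage[, j],
    sex = cohort$sex,
    gest = cohort$gestational_age
  )
  if (!adjust_maternal) d$mother <- NULL
  keep <- complete.cases(d)
  n_dropped <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  # constant precision covariates (e.g. sex in a single-sex subset) carry
  # no information and are dropped; a constant dosage stays fatal below
  for (cv in intersect(c("sex", "gest"), names(d)))
    if (nrow(d) && var(d[[cv]]) == 0) d[[cv]] <- NULL
  p <- ncol(d) # parameters incl. intercept (y column stands in for it)
  if (nrow(d) < p + 10)
    stop("too few complete rows (", nrow(d), ") to fit ", p,
         " parameters for ", snp_id, "/", outcome, call. = FALSE)
  fit <- lm(y ~ ., data = d)
  if (any(is.na(coef(fit))))
    stop("rank-deficient design for ", snp_id, "/", outcome,
         " (constant dosage or collinear covariates)", call. = FALSE)
  s <- summary(fit)$coefficients
  data.frame(cohort = cohort$cohort, snp_id = snp_id, outcome = outcome,
             beta = s["child", 1], se = s["child", 2],
             n_used = nrow(d), n_dropped = n_dropped,
             stringsAsFactors = FALSE)
}

#' Fixed-effects meta-analysis of one SNP-outcome association across cohorts
#'
#' Pools the per-cohort estimates with inverse-variance weights (delegating
#' to [pool_fixed()]) and reports between-cohort heterogeneity.
#'
#' @param assocs Data.frame of per-cohort rows from [fit_snp_model()], all
#'   for one `snp_id` and one `outcome` (asserted).
#' @return One-row data.frame: `snp_id`, `outcome`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pval`, `k_cohorts`, `q_stat`, `q_df`, `i2`, `n_total`.
#' @export
meta_across_cohorts <- function(assocs) {
  if (length(unique(assocs$snp_id)) != 1 ||
      length(unique(assocs$outcome)) != 1)
    stop("integrity error: meta_across_cohorts expects one snp_id and one ",
         "outcome", call. = FALSE)
  pooled <- pool_fixed(assocs$beta, assocs$se)
  data.frame(snp_id = assocs$snp_id[1], outcome = assocs$outcome[1],
             beta = pooled$estimate, se = pooled$se,
             ci_low = pooled$ci_low, ci_high = pooled$ci_high,
             pval = pooled$pval, k_cohorts = pooled$k,
             q_stat = pooled$q_stat, q_df = pooled$q_df, i2 = pooled$i2,
             n_total = sum(assocs$n_used), stringsAsFactors = FALSE)
}

#' Apply birth-record exclusion rules to a cohort
#'
#' Mirrors the quality filters applied to self-reported birth weights:
#' births below a minimum weight (a proxy for excluding preterm births when
#' gestational age is unrecorded), multiple births, and records whose two
#' birth-weight reports disagree by more than a tolerance.
#'
#' @param cohort A `duo_cohort`.
#' @param min_birthweight_g Minimum birth weight in grams (default 2200);
#'   `NA` disables the rule.
#' @param drop_multiple_births Drop duos flagged `multiple_birth`.
#' @param max_report_discrepancy_g Maximum tolerated absolute difference
#'   between `birth_weight_g` and `birth_weight_report2_g` (default 500);
#'   `NA` disables.
#' @return List with `cohort` (filtered) and `counts` (named integer vector
#'   of exclusions per rule). An empty filtered cohort is permitted but
#'   flagged with a warning.
#' @export
apply_exclusions <- function(cohort, min_birthweight_g = 2200,
                             drop_multiple_births = TRUE,
                             max_report_discrepancy_g = 500) {
  out <- cohort$outcomes
  n <- nrow(out)
  drop <- rep(FALSE, n)
  counts <- c(low_birthweight = 0L, multiple_birth = 0L,
              report_discrepancy = 0L)
  if (!is.na(min_birthweight_g) && "birth_weight_g" %in% names(out)) {
    hit <- !is.na(out$birth_weight_g) & out$birth_weight_g < min_birthweight_g
    counts["low_birthweight"] <- sum(hit & !drop)
    drop <- drop | hit
  }
  if (drop_multiple_births && "multiple_birth" %in% names(out)) {
    hit <- !is.na(out$multiple_birth) & out$multiple_birth
    counts["multiple_birth"] <- sum(hit & !drop)
    drop <- drop | hit
  }
  if (!is.na(max_report_discrepancy_g) &&
      all(c("birth_weight_g", "birth_weight_report2_g") %in% names(out))) {
    disc <- abs(out$birth_weight_g - out$birth_weight_report2_g)
    hit <- !is.na(disc) & disc > max_report_discrepancy_g
    counts["report_discrepancy"] <- sum(hit & !drop)
    drop <- drop | hit
  }
  keep <- !drop
  cohort$outcomes <- out[keep, , drop = FALSE]
  cohort$maternal_dosage <- cohort$maternal_dosage[keep, , drop = FALSE]
  cohort$child_dosage <- cohort$child_dosage[keep, , drop = FALSE]
  cohort$sex <- cohort$sex[keep]
  cohort$gestational_age <- cohort$gestational_age[keep]
  if (!nrow(cohort$outcomes))
    warning("all rows excluded from cohort '", cohort$cohort, "'")
  list(cohort = cohort, counts = counts)
}

#' Run the per-SNP cohort models across several cohorts and pool
#'
#' Convenience wrapper for the exploratory individual-level stage:
#' standardizes outcomes within each cohort, fits every SNP-outcome model
#' per cohort, then pools each SNP-outcome association across cohorts with
#' fixed-effects meta-analysis.
#'
#' @param cohorts List of `duo_cohort` objects (>= 2).
#' @param outcomes Outcome columns to analyse.
#' @param adjust_maternal Passed to [fit_snp_model()].
#' @return List with `per_cohort` (all cohort-level rows) and `pooled`
#'   (one row per SNP-outcome with heterogeneity statistics).
#' @export
cohort_pipeline <- function(cohorts, outcomes = "birth_weight_sd",
                            adjust_maternal = TRUE) {
  if (length(cohorts) < 2)
    stop("cohort_pipeline needs at least 2 cohorts", call. = FALSE)
  cohorts <- lapply(cohorts, standardize_outcomes, outcomes = outcomes)
  per <- do.call(rbind, lapply(cohorts, function(co) {
    do.call(rbind, lapply(outcomes, function(oc) {
      do.call(rbind, lapply(co$snp_ids, function(s)
        fit_snp_model(co, s, outcome = oc,
                      adjust_maternal = adjust_maternal)))
    }))
  }))
  keys <- unique(per[c("snp_id", "outcome")])
  pooled <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- per[per$snp_id == keys$snp_id[i] &
                 per$outcome == keys$outcome[i], , drop = FALSE]
    meta_across_cohorts(sub)
  }))
  rownames(per) <- rownames(pooled) <- NULL
  list(per_cohort = per, pooled = pooled)
}
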