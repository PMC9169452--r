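# Allele harmonization and instrument QC.
#
# Two-sample summary statistics report effects relative to an arbitrary
# allele and strand. Before pooling, every outcome effect must refer to the
# same physical allele as the exposure effect (the adiposity-raising allele).
# Non-palindromic SNPs are resolved by comparing allele labels directly,
# after swapping effect/other, after complementing the strand, and after
# both. Palindromic SNPs (A/T, C/G) are strand-ambiguous by construction and
# can only be oriented by allele frequency.

.complement <- function(a) chartr("ACGT", "TGCA", a)

.is_palindromic <- function(ea, oa) oa == .complement(ea)

#' Harmonize one exposure/outcome summary-statistic pair
#'
#' Aligns the outcome record so its effect allele is the exposure's effect
#' allele. Allele pairs are compared directly, then after swapping effect and
#' other allele, then after base-complementing (strand flip), then after
#' both; a swap negates the outcome beta and maps its `eaf` to `1 - eaf`.
#' Palindromic SNPs are oriented by frequency alone: the pair is alignable
#' only when both minor-allele frequencies are at most
#' `palindrome_freq_limit` (so the frequency signal is unambiguous); the
#' outcome beta is kept when both effect-allele frequencies fall on the same
#' side of 0.5 and negated otherwise. Otherwise the SNP is dropped.
#'
#' @param exposure,outcome Single-row canonical summary-statistic
#'   data.frames (or one-row slices) sharing `snp_id`.
#' @param palindrome_freq_limit Maximum minor-allele frequency at which a
#'   palindromic SNP is considered frequency-resolvable (default 0.42,
#'   standard two-sample harmonization practice).
#' @param palindromic_action `"freq"` to orient palindromic SNPs by
#'   frequency where possible, `"drop"` to always drop them.
#' @return One-row data.frame with `snp_id`, `aligned_exposure_beta`,
#'   `exposure_se`, `aligned_outcome_beta`, `outcome_se`, `outcome_eaf` and
#'   `resolution` (one of `direct`, `swap`, `strand_flip`,
#'   `strand_flip_swap`, `palindromic_freq`, `dropped`); a dropped SNP
#'   carries `NA` betas.
#' @export
harmonize_record <- function(exposure, outcome, palindrome_freq_limit = 0.42,
                             palindromic_action = c("freq", "drop")) {
  palindromic_action <- match.arg(palindromic_action)
  if (exposure$snp_id != outcome$snp_id)
    stop("harmonize_record: snp_id mismatch (", exposure$snp_id, " vs ",
         outcome$snp_id, ")", call. = FALSE)
  e1 <- exposure$effect_allele; o1 <- exposure$other_allele
  e2 <- outcome$effect_allele;  o2 <- outcome$other_allele

  res <- function(resolution, flip_sign = FALSE) {
    dropped <- resolution == "dropped"
    data.frame(
      snp_id = exposure$snp_id,
      aligned_exposure_beta = if (dropped) NA_real_ else exposure$beta,
      exposure_se = if (dropped) NA_real_ else exposure$se,
      aligned_outcome_beta = if (dropped) NA_real_ else
        if (flip_sign) -outcome$beta else outcome$beta,
      outcome_se = if (dropped) NA_real_ else outcome$se,
      outcome_eaf = if (dropped) NA_real_ else
        if (flip_sign && !is.na(outcome$eaf)) 1 - outcome$eaf
        else outcome$eaf,
      resolution = resolution,
      stringsAsFactors = FALSE
    )
  }

  if (.is_palindromic(e1, o1)) {
    # outcome must carry the same (self-complementary) allele set
    if (!setequal(c(e2, o2), c(e1, o1)))
      stop("allele mismatch for palindromic SNP ", exposure$snp_id, ": ",
           e1, "/", o1, " vs ", e2, "/", o2, call. = FALSE)
    if (palindromic_action == "drop") return(res("dropped"))
    if (is.na(exposure$eaf) || is.na(outcome$eaf))
      stop("palindromic SNP ", exposure$snp_id,
           " cannot be resolved: missing effect-allele frequency",
           call. = FALSE)
    maf <- function(f) pmin(f, 1 - f)
    if (maf(exposure$eaf) > palindrome_freq_limit ||
        maf(outcome$eaf) > palindrome_freq_limit)
      return(res("dropped"))
    same_side <- (exposure$eaf - 0.5) * (outcome$eaf - 0.5) > 0
    return(res("palindromic_freq", flip_sign = !same_side))
  }

  if (e2 == e1 && o2 == o1) return(res("direct"))
  if (e2 == o1 && o2 == e1) return(res("swap", flip_sign = TRUE))
  fe1 <- .complement(e1); fo1 <- .complement(o1)
  if (e2 == fe1 && o2 == fo1) return(res("strand_flip"))
  if (e2 == fo1 && o2 == fe1) return(res("strand_flip_swap", flip_sign = TRUE))
  stop("allele mismatch for SNP ", exposure$snp_id, ": ", e1, "/", o1,
       " vs ", e2, "/", o2, " cannot be reconciled", call. = FALSE)
}

#' Harmonize a joined instrument/outcome table
#'
#' Applies [harmonize_record()] to every row of a join produced by
#' [join_instruments()]. When `align_to_raising = TRUE` (the default),
#' instruments reported on the lowering allele (negative exposure beta) are
#' first flipped to their raising allele, so every aligned exposure beta is
#' non-negative and the pooled outcome effect reads as "per
#' adiposity-raising allele".
#'
#' @param pairs The `pairs` data.frame from [join_instruments()].
#' @param palindrome_freq_limit,palindromic_action Passed to
#'   [harmonize_record()].
#' @param align_to_raising Flip exposure records with negative beta to the
#'   opposite allele before harmonizing.
#' @return Data.frame of harmonized rows (one per input SNP, including
#'   dropped ones, flagged by `resolution == "dropped"`).
#' @export
harmonize_pairs <- function(pairs, palindrome_freq_limit = 0.42,
                            palindromic_action = c("freq", "drop"),
                            align_to_raising = TRUE) {
  palindromic_action <- match.arg(palindromic_action)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    exposure <- data.frame(
      snp_id = pairs$snp_id[i],
      effect_allele = pairs$exposure_effect_allele[i],
      other_allele = pairs$exposure_other_allele[i],
      eaf = pairs$exposure_eaf[i],
      beta = pairs$exposure_beta[i],
      se = pairs$exposure_se[i],
      stringsAsFactors = FALSE
    )
    if (align_to_raising && !is.na(exposure$beta) && exposure$beta < 0) {
      exposure[c("effect_allele", "other_allele")] <-
        exposure[c("other_allele", "effect_allele")]
      exposure$beta <- -exposure$beta
      exposure$eaf <- 1 - exposure$eaf
    }
    outcome <- data.frame(
      snp_id = pairs$snp_id[i],
      effect_allele = pairs$outcome_effect_allele[i],
      other_allele = pairs$outcome_other_allele[i],
      eaf = pairs$outcome_eaf[i],
      beta = pairs$outcome_beta[i],
      se = pairs$outcome_se[i],
      stringsAsFactors = FALSE
    )
    out[[i]] <- harmonize_record(exposure, outcome,
                                 palindrome_freq_limit = palindrome_freq_limit,
                                 palindromic_action = palindromic_action)
  }
  do.call(rbind, out)
}

#' Pairwise linkage-disequilibrium r-squared from dosages
#'
#' Squared Pearson correlation between two per-individual dosage vectors —
#' the r2 used to verify that instrument SNPs are mutually independent.
#'
#' @param dosages_a,dosages_b Numeric vectors of equal length (>= 2) of
#'   effect-allele dosages.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_ld_r2 <- function(dosages_a, dosages_b) {
  if (length(dosages_a) != length(dosages_b))
    stop("dosage vectors differ in length", call. = FALSE)
  if (length(dosages_a) < 2)
    stop("need at least 2 individuals", call. = FALSE)
  if (var(dosages_a) == 0 || var(dosages_b) == 0)
    stop("degenerate input: constant dosage vector", call. = FALSE)
  cor(dosages_a, dosages_b)^2
}

#' Filter an instrument set by exclusion list and pairwise LD
#'
#' Removes explicitly excluded SNPs (e.g. a variant whose trait association
#' is attributable to collider bias with disease status) and, for every
#' supplied LD pair with r2 above `r2_limit`, the member with the weaker
#' (larger p-value) exposure association — a tie-break users can override by
#' pre-specifying `exclude_ids`. Every removal is logged with its reason.
#'
#' @param instruments Instrument set or canonical data.frame.
#' @param exclude_ids Character vector of SNP ids to drop unconditionally;
#'   ids not present raise a warning, not an error.
#' @param ld_pairs Optional data.frame with columns `id_a`, `id_b`, `r2`.
#' @param r2_limit LD pruning threshold; pairs with `r2 > r2_limit` lose one
#'   member.
#' @return List with `instruments` (the filtered set, class preserved) and
#'   `log` (data.frame `snp_id`, `reason`).
#' @export
filter_instruments <- function(instruments, exclude_ids = character(),
                               ld_pairs = NULL, r2_limit = 0.05) {
  log <- data.frame(snp_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  keep <- as.data.frame(instruments)

  absent <- setdiff(exclude_ids, keep$snp_id)
  if (length(absent))
    warning("exclusion id(s) not present: ", paste(absent, collapse = ", "))
  hit <- intersect(exclude_ids, keep$snp_id)
  if (length(hit)) {
    log <- rbind(log, data.frame(snp_id = hit, reason = "explicit exclusion",
                                 stringsAsFactors = FALSE))
    keep <- keep[!keep$snp_id %in% hit, , drop = FALSE]
  }

  if (!is.null(ld_pairs) && nrow(ld_pairs)) {
    for (i in seq_len(nrow(ld_pairs))) {
      if (ld_pairs$r2[i] <= r2_limit) next
      a <- ld_pairs$id_a[i]; b <- ld_pairs$id_b[i]
      both <- c(a, b)[c(a, b) %in% keep$snp_id]
      if (length(both) < 2) next
      p <- keep$pval[match(both, keep$snp_id)]
      # drop the weaker instrument; ties (or missing p) drop the second
      drop_id <- if (!anyNA(p) && p[1] > p[2]) both[1] else both[2]
      log <- rbind(log, data.frame(
        snp_id = drop_id,
        reason = sprintf("LD with %s (r2 = %.3g > %.3g)",
                         setdiff(both, drop_id), ld_pairs$r2[i], r2_limit),
        stringsAsFactors = FALSE))
      keep <- keep[keep$snp_id != drop_id, , drop = FALSE]
    }
  }

  rownames(keep) <- NULL
  if (inherits(instruments, "instrument_set"))
    keep <- instrument_set(keep, name = attr(instruments, "name"),
                           trait_units = attr(instruments, "trait_units"))
  list(instruments = keep, log = log)
}
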