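# Independent oracles used across the suite. These re-derive every result
# from first principles (explicit formulas, enumeration, or a different
# estimator) and never call the code paths they check.

# --- meta-analysis: direct evaluation of the inverse-variance formulas ----
oracle_fixed <- function(b, s) {
  w <- 1 / s^2
  est <- sum(w * b) / sum(w)
  list(est = est, se = sqrt(1 / sum(w)), q = sum(w * (b - est)^2))
}

oracle_dl <- function(b, s) {
  fe <- oracle_fixed(b, s)
  k <- length(b)
  w <- 1 / s^2
  tau2 <- max(0, (fe$q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (s^2 + tau2)
  i2 <- if (fe$q > 0) max(0, (fe$q - (k - 1)) / fe$q) * 100 else 0
  list(est = sum(ws * b) / sum(ws), se = sqrt(1 / sum(ws)),
       q = fe$q, tau2 = tau2, i2 = i2)
}

# --- weighted least squares: normal-equations solution -------------------
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  beta <- solve(XtWX, t(X) %*% (w * y))
  res <- y - X %*% beta
  sigma2 <- sum(w * res^2) / (length(y) - 2)
  se <- sqrt(diag(solve(XtWX)) * sigma2)
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * res^2) / sum(w * (y - ybar)^2)
  k <- length(y)
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       intercept_se = unname(se[1]), slope_se = unname(se[2]),
       r2 = r2, adj_r2 = 1 - (1 - r2) * (k - 1) / (k - 2))
}

# --- harmonization: exhaustive configuration enumeration -----------------
# A ground-truth SNP has exposure alleles (ea, oa), exposure eaf f_exp, and
# an outcome beta b referring to the same physical allele as the exposure's
# effect allele, with outcome eaf f_out on the same side of 0.5 as f_exp.
# The outcome record can legitimately reach us in 8 configurations:
# {as-is, allele swap} x {reported strand, complementary strand} x (for the
# swap, beta sign and eaf reflected). The oracle says what the aligned
# outcome beta must be: +b whenever the record's stated effect allele is
# physically the exposure effect allele, -b otherwise; for palindromic
# SNPs label information is void and the frequency-consistent choice wins.
flip_base <- function(a) chartr("ACGT", "TGCA", a)

outcome_configurations <- function(ea, oa, f_out, b, se = 0.01,
                                   snp_id = "rs1") {
  mk <- function(e2, o2, beta, eaf, label)
    list(record = data.frame(snp_id = snp_id, effect_allele = e2,
                             other_allele = o2, eaf = eaf, beta = beta,
                             se = se, stringsAsFactors = FALSE),
         aligned_beta = b, label = label)
  list(
    mk(ea, oa, b, f_out, "direct"),
    mk(oa, ea, -b, 1 - f_out, "swap"),
    mk(flip_base(ea), flip_base(oa), b, f_out, "strand_flip"),
    mk(flip_base(oa), flip_base(ea), -b, 1 - f_out, "strand_flip_swap")
  )
}

# frequency-consistency oracle for palindromic SNPs: among the two physical
# readings of the record (keep beta / negate beta) pick the one whose
# implied effect-allele frequency is closer to the exposure's
oracle_palindromic_sign <- function(f_exp, eaf_out) {
  if (abs(eaf_out - f_exp) <= abs((1 - eaf_out) - f_exp)) 1 else -1
}

# --- misc -----------------------------------------------------------------
exposure_record <- function(snp_id = "rs1", ea = "A", oa = "G", eaf = 0.3,
                            beta = 0.05, se = 0.01) {
  data.frame(snp_id = snp_id, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se, stringsAsFactors = FALSE)
}

make_sumstats <- function(n, seed = 1, prefix = "rs") {
  set.seed(seed)
  alleles <- rbind(c("A", "G"), c("C", "T"), c("G", "A"), c("A", "C"))
  pick <- alleles[(seq_len(n) - 1) %% 4 + 1, , drop = FALSE]
  data.frame(
    snp_id = paste0(prefix, seq_len(n)),
    chrom = as.character(rep(1:22, length.out = n)),
    pos = seq_len(n) * 1000 + 1,
    effect_allele = pick[, 1], other_allele = pick[, 2],
    eaf = runif(n, 0.05, 0.95),
    beta = rnorm(n, 0, 0.02), se = runif(n, 0.001, 0.01),
    pval = runif(n), n = 100000, stringsAsFactors = FALSE
  )
}
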