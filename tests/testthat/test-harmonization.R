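test_that("non-palindromic records align in all four label configurations", {
  exp <- exposure_record(ea = "A", oa = "G", eaf = 0.3, beta = 0.05)
  configs <- outcome_configurations("A", "G", f_out = 0.31, b = 0.012)
  for (cf in configs) {
    h <- harmonize_record(exp, cf$record)
    expect_equal(h$resolution, cf$label)
    expect_equal(h$aligned_outcome_beta, cf$aligned_beta, tolerance = 1e-12)
    expect_equal(h$outcome_se, 0.01)
    expect_equal(h$outcome_eaf, 0.31, tolerance = 1e-12)
  }
})

test_that("harmonization is idempotent and anti-symmetric in allele order", {
  exp <- exposure_record(ea = "C", oa = "T", eaf = 0.6, beta = 0.04)
  out <- exposure_record(ea = "C", oa = "T", eaf = 0.62, beta = -0.008,
                         se = 0.002)
  h1 <- harmonize_record(exp, out)
  expect_equal(h1$resolution, "direct")
  expect_equal(h1$aligned_outcome_beta, -0.008)

  # swapping the outcome's alleles flips the sign, leaves the SE alone
  swapped <- out
  swapped[c("effect_allele", "other_allele")] <-
    out[c("other_allele", "effect_allele")]
  swapped$beta <- -out$beta
  swapped$eaf <- 1 - out$eaf
  h2 <- harmonize_record(exp, swapped)
  expect_equal(h2$aligned_outcome_beta, h1$aligned_outcome_beta)
  expect_equal(h2$outcome_se, h1$outcome_se)

  # complementing both alleles of the outcome never changes the result
  comp <- out
  comp$effect_allele <- flip_base(out$effect_allele)
  comp$other_allele <- flip_base(out$other_allele)
  h3 <- harmonize_record(exp, comp)
  expect_equal(h3$aligned_outcome_beta, h1$aligned_outcome_beta)
})

test_that("palindromic SNPs follow the exhaustive frequency oracle", {
  # 8 configurations (4 label layouts x 2 eaf orientations) under three
  # frequency regimes: resolvable low-MAF, resolvable high-EAF, ambiguous
  for (f_exp in c(0.10, 0.88)) {
    exp <- exposure_record(ea = "A", oa = "T", eaf = f_exp, beta = 0.05)
    for (layout in list(c("A", "T"), c("T", "A"))) {
      for (eaf_out in c(0.12, 0.88)) {
        out <- data.frame(snp_id = "rs1", effect_allele = layout[1],
                          other_allele = layout[2], eaf = eaf_out,
                          beta = 0.02, se = 0.01, stringsAsFactors = FALSE)
        h <- harmonize_record(exp, out, palindrome_freq_limit = 0.42)
        expect_equal(h$resolution, "palindromic_freq")
        expect_equal(h$aligned_outcome_beta,
                     0.02 * oracle_palindromic_sign(f_exp, eaf_out),
                     info = sprintf("f_exp=%g layout=%s eaf=%g", f_exp,
                                    paste(layout, collapse = "/"), eaf_out))
      }
    }
  }
  # worked example: A/T exposure eaf 0.10 vs outcome eaf 0.88 flips the sign
  exp <- exposure_record(ea = "A", oa = "T", eaf = 0.10, beta = 0.05)
  out <- exposure_record(ea = "A", oa = "T", eaf = 0.88, beta = 0.02)
  h <- harmonize_record(exp, out, palindrome_freq_limit = 0.42)
  expect_equal(h$aligned_outcome_beta, -0.02)
  expect_equal(h$resolution, "palindromic_freq")
})

test_that("ambiguous or frequency-less palindromic SNPs drop or error", {
  exp <- exposure_record(ea = "C", oa = "G", eaf = 0.47, beta = 0.03)
  out <- exposure_record(ea = "C", oa = "G", eaf = 0.48, beta = 0.01)
  h <- harmonize_record(exp, out, palindrome_freq_limit = 0.42)
  expect_equal(h$resolution, "dropped")
  expect_true(is.na(h$aligned_outcome_beta))

  out$eaf <- NA_real_
  expect_error(harmonize_record(exp, out), "missing effect-allele frequency")

  low <- exposure_record(ea = "C", oa = "G", eaf = 0.10, beta = 0.03)
  out2 <- exposure_record(ea = "C", oa = "G", eaf = 0.12, beta = 0.01)
  h2 <- harmonize_record(low, out2, palindromic_action = "drop")
  expect_equal(h2$resolution, "dropped")
})

test_that("irreconcilable allele sets raise a mismatch naming the SNP", {
  exp <- exposure_record(snp_id = "rs77", ea = "A", oa = "G")
  out <- exposure_record(snp_id = "rs77", ea = "A", oa = "C")
  expect_error(harmonize_record(exp, out), "rs77")
})

test_that("harmonize_pairs flips instruments to the raising allele", {
  ins <- make_sumstats(6, seed = 11)
  ins$beta <- c(0.02, -0.03, 0.01, -0.005, 0.04, 0.02)
  outcome <- ins
  outcome$beta <- 0.5 * ins$beta + 0.001  # proportional outcome, same EA
  h <- harmonize_pairs(join_instruments(instrument_set(ins), outcome)$pairs)
  expect_true(all(h$aligned_exposure_beta >= 0))
  # flipping exposure to the raising allele must flip the outcome with it
  expect_equal(h$aligned_outcome_beta,
               ifelse(ins$beta < 0, -1, 1) * outcome$beta)
})

test_that("pairwise LD r2 equals the closed-form Pearson value", {
  expect_equal(pairwise_ld_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1.0)
  expect_equal(pairwise_ld_r2(c(0, 1, 2, 0), c(0, 1, 1, 0)), 0.8182,
               tolerance = 1e-4)
  set.seed(42)
  g1 <- rbinom(10000, 2, 0.3)
  g2 <- rbinom(10000, 2, 0.3)
  expect_lt(pairwise_ld_r2(g1, g2), 0.01)
  expect_error(pairwise_ld_r2(rep(1, 5), g2[1:5]), "degenerate")
  expect_error(pairwise_ld_r2(1, 1), "at least 2")
})

test_that("instrument filtering reproduces the exclusion bookkeeping", {
  ins77 <- instrument_set(make_sumstats(77, seed = 12), name = "bmi")
  f <- filter_instruments(ins77, exclude_ids = "rs7")
  expect_equal(nrow(f$instruments), 76)
  expect_equal(f$log$reason, "explicit exclusion")

  ins393 <- instrument_set(make_sumstats(393, seed = 13))
  ld <- data.frame(id_a = "rs10", id_b = "rs20", r2 = 0.5)
  f2 <- filter_instruments(ins393, ld_pairs = ld, r2_limit = 0.4)
  expect_equal(nrow(f2$instruments), 392)
  expect_match(f2$log$reason, "LD")
  # the member with the larger exposure p-value is the one removed
  p <- ins393$pval[match(c("rs10", "rs20"), ins393$snp_id)]
  expect_equal(f2$log$snp_id, c("rs10", "rs20")[which.max(p)])

  # below the limit nothing happens; identity on empty inputs
  f3 <- filter_instruments(ins393, ld_pairs = data.frame(
    id_a = "rs10", id_b = "rs20", r2 = 0.3), r2_limit = 0.4)
  expect_equal(nrow(f3$instruments), 393)
  f4 <- filter_instruments(ins77)
  expect_equal(as.data.frame(f4$instruments), as.data.frame(ins77))
  expect_warning(filter_instruments(ins77, exclude_ids = "rs9999"),
                 "not present")
})
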