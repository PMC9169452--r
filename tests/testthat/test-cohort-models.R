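test_that("standardization is a fixed point on z-scored data and derives PI", {
  co <- simulate_duo_cohort(duo_config(n_individuals = 2000, n_snps = 2,
                                       seed = 81))
  z <- standardize_outcomes(co)
  for (col in c("birth_weight_sd", "birth_length_cm"))
    expect_equal(c(mean(z$outcomes[[col]]), sd(z$outcomes[[col]])),
                 c(0, 1), tolerance = 1e-12)
  z2 <- standardize_outcomes(z)
  expect_equal(z2$outcomes$birth_weight_sd, z$outcomes$birth_weight_sd,
               tolerance = 1e-12)

  # ponderal index derived from the raw columns before z-scoring:
  # 3.5 kg at 0.50 m is 28 kg/m^3
  co$outcomes$birth_weight_g[1] <- 3500
  co$outcomes$birth_length_cm[1] <- 50
  raw <- standardize_outcomes(co, outcomes = "birth_weight_sd")
  expect_equal(raw$outcomes$ponderal_index_kg_m3[1], 28.0)

  co$outcomes$birth_length_cm <- 50
  expect_error(standardize_outcomes(co, outcomes = "birth_length_cm"),
               "birth_length_cm")
})

test_that("per-SNP fit removes the maternal confounding of the child effect", {
  cfg <- duo_config(n_individuals = 10000, n_snps = 1, allele_freqs = 0.4,
                    beta_fetal = 0.1, beta_maternal = 0.2, seed = 82)
  co <- standardize_outcomes(simulate_duo_cohort(cfg),
                             outcomes = "birth_weight_sd")
  # standardization shrinks the scale by sd(bw); undo for comparability
  scale_back <- sd(simulate_duo_cohort(cfg)$outcomes$birth_weight_sd)
  adj <- fit_snp_model(co, co$snp_ids[1], "birth_weight_sd",
                       adjust_maternal = TRUE)
  una <- fit_snp_model(co, co$snp_ids[1], "birth_weight_sd",
                       adjust_maternal = FALSE)
  # transmission expectation: unadjusted ~ bF + bM/2 = 0.2, adjusted ~ 0.1
  expect_lt(abs(una$beta * scale_back - 0.2), 3 * una$se)
  expect_lt(abs(adj$beta * scale_back - 0.1), 3 * adj$se)
  expect_gt(una$beta, adj$beta)
})

test_that("a genotype-independent covariate does not move the estimate", {
  cfg <- duo_config(n_individuals = 8000, n_snps = 1, allele_freqs = 0.5,
                    beta_fetal = 0.08, seed = 83)
  co <- standardize_outcomes(simulate_duo_cohort(cfg),
                             outcomes = "birth_weight_sd")
  all_fit <- fit_snp_model(co, co$snp_ids[1], "birth_weight_sd")
  subset_cohort <- function(keep) {
    co2 <- co
    co2$outcomes <- co$outcomes[keep, , drop = FALSE]
    co2$child_dosage <- co$child_dosage[keep, , drop = FALSE]
    co2$maternal_dosage <- co$maternal_dosage[keep, , drop = FALSE]
    co2$sex <- co$sex[keep]; co2$gestational_age <- co$gestational_age[keep]
    co2
  }
  f_fit <- fit_snp_model(subset_cohort(co$sex == 0), co$snp_ids[1],
                         "birth_weight_sd")
  m_fit <- fit_snp_model(subset_cohort(co$sex == 1), co$snp_ids[1],
                         "birth_weight_sd")
  pooled_se <- sqrt(f_fit$se^2 + m_fit$se^2)
  expect_lt(abs(f_fit$beta - m_fit$beta), 3 * pooled_se)
  expect_lt(abs(all_fit$beta - f_fit$beta), 3 * f_fit$se)
})

test_that("betas are invariant to the outcome's measurement scale", {
  co <- simulate_duo_cohort(duo_config(n_individuals = 3000, n_snps = 1,
                                       beta_fetal = 0.1, seed = 84))
  a <- fit_snp_model(standardize_outcomes(co, "birth_weight_sd"),
                     co$snp_ids[1], "birth_weight_sd")
  co$outcomes$birth_weight_sd <- co$outcomes$birth_weight_sd * 484
  b <- fit_snp_model(standardize_outcomes(co, "birth_weight_sd"),
                     co$snp_ids[1], "birth_weight_sd")
  expect_equal(a$beta, b$beta, tolerance = 1e-10)
  expect_equal(a$se, b$se, tolerance = 1e-10)
})

test_that("rank-deficient designs and tiny cohorts are refused", {
  co <- simulate_duo_cohort(duo_config(n_individuals = 3000, n_snps = 1,
                                       seed = 85))
  co$child_dosage[, 1] <- 1L
  expect_error(fit_snp_model(co, co$snp_ids[1], "birth_weight_sd"),
               "rank-deficient")
  tiny <- simulate_duo_cohort(duo_config(n_individuals = 12, n_snps = 1,
                                         seed = 86))
  expect_error(fit_snp_model(tiny, tiny$snp_ids[1], "birth_weight_sd"),
               "too few")
})

test_that("cross-cohort pooling matches the closed form and flags mixtures", {
  assocs <- data.frame(cohort = c("a", "b"), snp_id = "rs1",
                       outcome = "bw", beta = c(0.1, 0.3), se = c(0.1, 0.1),
                       n_used = c(500, 600))
  m <- meta_across_cohorts(assocs)
  expect_lt(abs(m$beta - 0.2), 1e-4)
  expect_lt(abs(m$se - 0.0707), 1e-4)
  expect_equal(m$n_total, 1100)

  dup <- assocs; dup$beta <- 0.1
  m2 <- meta_across_cohorts(dup)
  expect_equal(m2$beta, 0.1)
  expect_equal(m2$se, 0.1 / sqrt(2))
  expect_equal(m2$q_stat, 0)

  mixed <- assocs; mixed$snp_id <- c("rs1", "rs2")
  expect_error(meta_across_cohorts(mixed), "integrity")
})

test_that("cohorts sharing a true effect show little heterogeneity", {
  i2s <- vapply(1:40, function(r) {
    assoc <- do.call(rbind, lapply(1:4, function(i) {
      co <- simulate_duo_cohort(duo_config(
        n_individuals = 1500, n_snps = 1, allele_freqs = 0.4,
        beta_fetal = 0.1, cohort = paste0("c", i), seed = 1000 * r + i))
      fit_snp_model(standardize_outcomes(co, "birth_weight_sd"),
                    co$snp_ids[1], "birth_weight_sd")
    }))
    meta_across_cohorts(assoc)$i2
  }, numeric(1))
  expect_lt(median(i2s), 25)
})

test_that("exclusion rules mirror the birth-record quality filters", {
  co <- simulate_duo_cohort(duo_config(n_individuals = 200, n_snps = 1,
                                       seed = 87))
  co$outcomes$birth_weight_g <- rep(3400, 200)
  co$outcomes$birth_weight_report2_g <- co$outcomes$birth_weight_g
  co$outcomes$multiple_birth <- FALSE
  co$outcomes$birth_weight_g[5] <- 2100              # below 2.2 kg
  co$outcomes$birth_weight_report2_g[5] <- 2100
  co$outcomes$multiple_birth[9] <- TRUE
  co$outcomes$birth_weight_report2_g[12] <-
    co$outcomes$birth_weight_g[12] + 600             # 0.6 kg discrepancy

  res <- apply_exclusions(co)
  expect_equal(unname(res$counts),
               c(1L, 1L, 1L))
  expect_equal(nrow(res$cohort$outcomes), 197)
  expect_equal(nrow(res$cohort$child_dosage), 197)

  # disabled thresholds are the identity
  res2 <- apply_exclusions(co, min_birthweight_g = NA,
                           drop_multiple_births = FALSE,
                           max_report_discrepancy_g = NA)
  expect_equal(nrow(res2$cohort$outcomes), 200)
  expect_equal(sum(res2$counts), 0L)
})

test_that("the cohort pipeline pools every SNP-outcome pair across cohorts", {
  cohorts <- lapply(1:2, function(i)
    simulate_duo_cohort(duo_config(n_individuals = 800, n_snps = 3,
                                   cohort = paste0("c", i),
                                   seed = 90 + i)))
  res <- cohort_pipeline(cohorts, outcomes = c("birth_weight_sd",
                                               "birth_length_cm"))
  expect_equal(nrow(res$per_cohort), 2 * 3 * 2)
  expect_equal(nrow(res$pooled), 3 * 2)
  expect_true(all(res$pooled$k_cohorts == 2))
  expect_error(cohort_pipeline(cohorts[1]), "at least 2")
})
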