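test_that("configuration validation names the offending field", {
  expect_error(sim_config(grs_liability_r2 = 1.2), "grs_liability_r2")
  expect_error(sim_config(outcome_prevalence = 0), "outcome_prevalence")
  expect_error(sim_config(maf_range = c(0.5, 0.1)), "maf_range")
  expect_error(sim_config(n_nights = 1), "n_nights")
  expect_error(sim_config(invalid_fraction = 1.5), "invalid_fraction")
})

test_that("genotype generator obeys Hardy-Weinberg marginals and determinism", {
  cfg0 <- sim_config(n_individuals = 200, n_snps = 5, maf_range = c(0, 0),
                     seed = 4)
  expect_true(all(simulate_genotypes(cfg0)$dosages == 0))

  cfg <- sim_config(n_individuals = 10000, n_snps = 8,
                    maf_range = c(0.5, 0.5), seed = 4)
  g <- simulate_genotypes(cfg)
  se <- sqrt(2 * 0.25 / cfg$n_individuals)
  expect_true(all(abs(colMeans(g$dosages) - 1) < 4 * se))

  g2 <- simulate_genotypes(cfg)
  expect_identical(g$dosages, g2$dosages)
  expect_identical(g$variants_extra, g2$variants_extra)
})

test_that("dosage means track twice the drawn allele frequency", {
  cfg <- sim_config(n_individuals = 20000, n_snps = 20, seed = 9)
  g <- simulate_genotypes(cfg)
  maf <- g$variants_extra$maf
  se <- sqrt(2 * maf * (1 - maf) / cfg$n_individuals)
  expect_true(all(abs(colMeans(g$dosages) - 2 * maf) < 4 * se))
})

test_that("exposure liability gives the GRS its configured variance share", {
  cfg0 <- sim_config(n_individuals = 5000, n_snps = 20,
                     grs_liability_r2 = 0, seed = 2)
  g0 <- simulate_genotypes(cfg0)
  c0 <- simulate_exposure(g0, cfg0)
  grs_true <- attr(c0, "truth")$grs_true
  expect_lt(abs(cor(grs_true, c0$liability)), 4 / sqrt(cfg0$n_individuals))

  cfg <- sim_config(n_individuals = 50000, n_snps = 50,
                    grs_liability_r2 = 0.054, seed = 2)
  g <- simulate_genotypes(cfg)
  co <- simulate_exposure(g, cfg)
  r2 <- cor(attr(co, "truth")$grs_true, co$liability)^2
  expect_lt(abs(r2 - 0.054), 0.01)

  # morning-person share matches the configured case fraction
  p <- mean(co$morning_person)
  ci_half <- qnorm(0.995) * sqrt(0.626 * (1 - 0.626) / cfg$n_individuals)
  expect_lt(abs(p - 0.626), ci_half + 1 / cfg$n_individuals)
})

test_that("outcome generator hits target prevalence and recovers null effects", {
  cfg <- sim_config(n_individuals = 20000, n_snps = 10, causal_lnor = 0,
                    confounder_effect_outcome = 0, outcome_prevalence = 0.11,
                    seed = 6)
  sim <- simulate_cohort(cfg)
  p <- mean(sim$cohort$depressive_symptoms)
  ci_half <- qnorm(0.995) * sqrt(0.11 * 0.89 / cfg$n_individuals)
  expect_lt(abs(p - 0.11), ci_half)
})

test_that("a randomised exposure design recovers the true causal log-OR", {
  # no genetic or confounder path: exposure is effectively randomised
  cfg <- sim_config(n_individuals = 20000, n_snps = 10, causal_lnor = -0.12,
                    grs_liability_r2 = 0, confounder_effect_exposure = 0,
                    confounder_effect_outcome = 0, seed = 8)
  sim <- simulate_cohort(cfg)
  fit <- fit_logistic(sim$cohort, "depressive_symptoms", "morning_person")
  co <- fit$coefficients[fit$coefficients$term == "morning_person", ]
  expect_lt(abs(co$beta - (-0.12)), 3 * co$se)
})

test_that("balanced pleiotropy draws are mean-zero and recorded in truth", {
  cfg <- sim_config(n_individuals = 500, n_snps = 400,
                    pleiotropy_mode = "balanced", invalid_fraction = 0.5,
                    pleiotropy_sd = 0.05, seed = 3)
  sim <- simulate_cohort(cfg)
  truth <- attr(sim$cohort, "truth")
  idx <- truth$invalid_idx
  expect_length(idx, 200)
  expect_lt(abs(mean(truth$gamma[idx])), 4 * 0.05 / sqrt(length(idx)))
  expect_true(all(truth$gamma[-idx] == 0))
})

test_that("ordinal scores respect their documented bounds", {
  cfg <- sim_config(n_individuals = 3000, n_snps = 10, seed = 5)
  ch <- simulate_cohort(cfg)$cohort
  expect_true(all(ch$phq9_severity >= 0 & ch$phq9_severity <= 27))
  expect_true(all(ch$gad_severity >= 0 & ch$gad_severity <= 21))
  expect_true(all(ch$wellbeing_score >= 3 & ch$wellbeing_score <= 17))
  expect_true(all(ch$cidi_severity >= 0))
  expect_false(anyNA(ch[, setdiff(names(ch), "participant_id")]))
})

test_that("two-sample stats come from disjoint samples and a causal ratio", {
  cfg <- sim_config(n_individuals = 8000, n_snps = 40, causal_lnor = -0.3,
                    grs_liability_r2 = 0.3, confounder_effect_exposure = 0,
                    confounder_effect_outcome = 0, seed = 10)
  ss <- make_two_sample_stats(cfg)
  expect_named(ss, c("exposure", "outcome"))
  expect_true(all(ss$exposure$se > 0) && all(ss$outcome$se > 0))
  expect_true(all(ss$exposure$effect_allele %in% c("A", "C", "G", "T")))
  # median per-SNP ratio tracks the causal slope of outcome on liability
  r <- ss$outcome$beta / ss$exposure$beta
  est <- ivw(data.frame(beta_exposure = ss$exposure$beta,
                        se_exposure = ss$exposure$se,
                        beta_outcome = ss$outcome$beta,
                        se_outcome = ss$outcome$se))
  # liability -> binary morningness -> outcome attenuates the slope, so we
  # only require a clearly negative, precisely estimated effect
  expect_lt(est$beta + 3 * est$se, 0)
})

test_that("full allele flipping is undone exactly by harmonisation", {
  cfg <- sim_config(n_individuals = 2000, n_snps = 25, seed = 12)
  ss0 <- make_two_sample_stats(cfg)
  cfg1 <- sim_config(n_individuals = 2000, n_snps = 25, seed = 12,
                     flip_fraction = 1)
  ss1 <- make_two_sample_stats(cfg1)
  h0 <- harmonise(ss0$exposure, ss0$outcome)
  h1 <- harmonise(ss1$exposure, ss1$outcome)
  expect_equal(h1$beta_outcome, h0$beta_outcome, tolerance = 1e-12)
  expect_equal(ivw(h1)$beta, ivw(h0)$beta, tolerance = 1e-12)
})

test_that("null summary-level outcome z-scores are standard normal", {
  ps <- vapply(1:40, function(s) {
    h <- simulate_summary_stats(80, true_effect = 0, seed = 1000 + s)
    z <- h$beta_outcome / h$se_outcome
    stats::ks.test(z, "pnorm")$p.value
  }, numeric(1))
  # p-values approximately uniform: KS test on the KS p-values
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("actigraphy generator is deterministic with CPD-ready structure", {
  cfg <- sim_config(n_individuals = 300, n_snps = 5, seed = 21)
  ch <- simulate_cohort(cfg)$cohort
  a1 <- simulate_actigraphy(ch, cfg)
  a2 <- simulate_actigraphy(ch, cfg)
  expect_identical(a1, a2)
  dur <- as.numeric(difftime(a1$sleep_offset, a1$sleep_onset, units = "hours"))
  expect_true(all(dur > 2 & dur < 16))
  expect_setequal(unique(table(a1$participant_id)), cfg$n_nights)
  # Friday/Saturday flagged as free nights
  wd <- as.integer(format(a1$date, "%u"))
  expect_identical(a1$is_free_night, wd %in% c(5L, 6L))
})

test_that("zero midpoint jitter collapses every participant's CPD to zero", {
  cfg <- sim_config(n_individuals = 50, n_snps = 5, act_jitter_morning = 0,
                    act_jitter_evening = 0, seed = 33)
  ch <- simulate_cohort(cfg)$cohort
  act <- simulate_actigraphy(ch, cfg)
  tab <- cpd_table(act)
  expect_true(all(abs(tab$cpd_primary) < 1e-9))
})

test_that("evening types accumulate more CPD than morning types", {
  cfg <- sim_config(n_individuals = 4000, n_snps = 5, seed = 14)
  ch <- simulate_cohort(cfg)$cohort
  act <- simulate_actigraphy(ch, cfg)
  tab <- cpd_table(act)
  m <- merge(tab, ch[, c("participant_id", "morning_person")])
  means <- tapply(m$cpd_primary, m$morning_person, mean)
  expect_lt(means[["1"]], means[["0"]])
})
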