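h_of <- function(bx, sx, by, sy) {
  h <- data.frame(beta_exposure = bx, se_exposure = sx,
                  beta_outcome = by, se_outcome = sy)
  class(h) <- c("harmonised_summary", "data.frame")
  h
}

test_that("summary-stat harmonisation aligns swapped and flipped alleles", {
  exp_s <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                      effect_allele = c("A", "C", "A"),
                      other_allele = c("G", "T", "G"),
                      eaf = c(0.3, 0.2, 0.4), beta = c(0.1, 0.2, 0.15),
                      se = c(0.01, 0.01, 0.01))
  out_s <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                      effect_allele = c("G", "C", "T"),   # swap, same, strand
                      other_allele = c("A", "T", "C"),
                      eaf = c(0.7, 0.2, 0.4), beta = c(0.05, 0.07, 0.02),
                      se = c(0.02, 0.02, 0.02))
  h <- harmonise(exp_s, out_s)
  expect_equal(h$beta_outcome, c(-0.05, 0.07, 0.02))
  expect_equal(nrow(attr(h, "dropped")), 0)
})

test_that("ambiguous palindromic SNPs are dropped with a reason", {
  exp_s <- data.frame(variant_id = c("rs1", "rs2"),
                      effect_allele = c("A", "A"), other_allele = c("T", "T"),
                      eaf = c(0.5, 0.10), beta = c(0.1, 0.1),
                      se = c(0.01, 0.01))
  out_s <- data.frame(variant_id = c("rs1", "rs2"),
                      effect_allele = c("A", "A"), other_allele = c("T", "T"),
                      eaf = c(0.5, 0.10), beta = c(0.05, 0.04),
                      se = c(0.02, 0.02))
  h <- harmonise(exp_s, out_s)
  expect_equal(h$variant_id, "rs2")          # rs1 is ambiguous at EAF 0.5
  dropped <- attr(h, "dropped")
  expect_equal(dropped$reason, "palindromic_ambiguous")
  expect_error(harmonise(exp_s[0, ], out_s), "overlapping")
})

test_that("Wald ratios follow their closed forms and sign invariance", {
  h <- h_of(c(1, 2), c(0.1, 0.1), c(0.5, 0.5), c(0.1, 0.1))
  re <- ratio_estimates(h)
  expect_equal(re$ratio, c(0.5, 0.25))
  expect_equal(re$se, c(0.1, 0.05))
  # joint sign flip leaves the ratio unchanged
  h2 <- h_of(c(-1, 2), c(0.1, 0.1), c(-0.5, 0.5), c(0.1, 0.1))
  expect_equal(ratio_estimates(h2)$ratio, re$ratio)
  expect_error(ratio_estimates(h_of(0, 0.1, 0.5, 0.1)), "zero")
})

test_that("IVW matches the weighted-least-squares closed form", {
  h <- h_of(c(1, 2), c(0.1, 0.1), c(0.5, 0.5), c(0.1, 0.1))
  est <- ivw(h)
  expect_equal(est$beta, 0.3)                # hand-computed WLS through origin
  # homogeneous ratios: estimate is the common ratio and Q = 0
  h0 <- h_of(c(0.5, 1, 2), c(0.1, 0.1, 0.1), c(0.15, 0.3, 0.6), rep(0.1, 3))
  e0 <- ivw(h0)
  expect_equal(e0$beta, 0.3, tolerance = 1e-12)
  expect_equal(e0$Q, 0, tolerance = 1e-12)
  # equal weights: equals OLS through the origin
  set.seed(31)
  h1 <- h_of(rnorm(20, 0.1, 0.02), rep(0.01, 20), rnorm(20, 0, 0.03),
             rep(0.02, 20))
  ols <- sum(h1$beta_exposure * h1$beta_outcome) / sum(h1$beta_exposure^2)
  expect_equal(ivw(h1)$beta, ols, tolerance = 1e-12)
})

test_that("IVW is unbiased under many valid instruments", {
  set.seed(77)
  est <- vapply(1:150, function(i)
    ivw(simulate_summary_stats(100, 0.2, seed = 7000 + i))$beta, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.2), 3 * mc_se)
})

test_that("MR-Egger reproduces the two-point line and recovers pleiotropy", {
  h <- h_of(c(1, 2), c(0.01, 0.01), c(0.3, 0.5), c(0.1, 0.1))
  est <- mr_egger(h_of(c(1, 2, 3), c(0.01, 0.01, 0.01), c(0.3, 0.5, 0.7),
                       rep(0.1, 3)))
  expect_equal(est$beta, 0.2, tolerance = 1e-12)       # exact-fit line
  expect_equal(est$intercept, 0.1, tolerance = 1e-12)
  expect_error(mr_egger(h), "3 SNPs")

  # directional pleiotropy: intercept estimates the mean direct effect
  set.seed(42)
  res <- vapply(1:60, function(i) {
    h <- simulate_summary_stats(150, 0.2, "directional",
                                invalid_fraction = 1, pleiotropy_sd = 0.03,
                                seed = 9000 + i)
    gam <- attr(h, "truth")$gamma
    e <- mr_egger(h)
    c(e$intercept - mean(gam), e$beta)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ])), 3 * sd(res[1, ]) / sqrt(ncol(res)))
  expect_lt(abs(mean(res[2, ]) - 0.2), 3 * sd(res[2, ]) / sqrt(ncol(res)))
})

test_that("Egger intercept p-values are uniform without pleiotropy", {
  ps <- vapply(1:150, function(i)
    mr_egger(simulate_summary_stats(100, 0.1, seed = 3000 + i))$intercept_p,
    numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("weighted median interpolates the hand-computed value", {
  # ratios 0.1/0.2/0.4, normalised weights 0.25/0.25/0.5
  wm <- chronomr:::weighted_median_point(c(0.1, 0.2, 0.4), c(1, 1, 2))
  expect_equal(wm, 0.2 + 0.2 * (0.5 - 0.375) / (0.75 - 0.375))
  expect_equal(round(wm, 4), 0.2667)
  # all ratios equal
  h0 <- h_of(c(1, 2, 4), rep(0.01, 3), c(0.3, 0.6, 1.2), rep(0.1, 3))
  expect_equal(weighted_median(h0, n_boot = 0)$beta, 0.3, tolerance = 1e-9)
  # equal weights and odd n: the plain median of ratios
  r <- c(0.1, 0.25, 0.4, 0.55, 0.7)
  h1 <- h_of(rep(1, 5), rep(0.01, 5), r, rep(0.1, 5))
  expect_equal(weighted_median(h1, n_boot = 0)$beta, median(r))
  expect_error(weighted_median(h_of(1, 0.1, 1, 0.1)), "3 SNPs")
})

test_that("weighted median resists directional pleiotropy better than IVW", {
  set.seed(55)
  res <- vapply(1:80, function(i) {
    h <- simulate_summary_stats(100, 0.2, "directional",
                                invalid_fraction = 0.4, seed = 11000 + i)
    c(abs(ivw(h)$beta - 0.2), abs(weighted_median(h, n_boot = 0)$beta - 0.2))
  }, numeric(2))
  expect_gte(mean(res[2, ] < res[1, ]), 0.95)
  expect_lt(mean(res[2, ]), 0.6 * mean(res[1, ]))
})

test_that("penalisation deactivates without outliers and tames a gross one", {
  set.seed(8)
  h <- simulate_summary_stats(30, 0.2, seed = 44)
  wm <- weighted_median(h, n_boot = 0)$beta
  pwm <- penalised_weighted_median(h, n_boot = 0)$beta
  re <- ratio_estimates(h)
  pj <- stats::pchisq(re$weight * (re$ratio - wm)^2, 1, lower.tail = FALSE)
  if (all(pj > 0.05)) expect_identical(pwm, wm)

  # one gross outlier among 20 concordant SNPs
  h2 <- h_of(rep(1, 21), rep(0.01, 21),
             c(rep(0.2, 20) + seq(-0.01, 0.009, by = 0.001), 5),
             rep(0.05, 21))
  re2 <- ratio_estimates(h2)
  b_wm <- chronomr:::weighted_median_point(re2$ratio, re2$weight)
  w_pen <- chronomr:::penalised_weights(re2$ratio, re2$weight, b_wm, 20)
  expect_lt(w_pen[21] / re2$weight[21], 0.01)
  est2 <- penalised_weighted_median(h2, n_boot = 0)$beta
  expect_lt(abs(est2 - 0.2), 0.02)

  # penalty -> infinity recovers the unpenalised estimator (all p_j > 0)
  expect_equal(penalised_weighted_median(h, penalty = 1e12, n_boot = 0)$beta,
               weighted_median(h, n_boot = 0)$beta)
})

test_that("heterogeneity Q follows its arithmetic and null distribution", {
  h0 <- h_of(c(1, 2), rep(0.01, 2), c(0.3, 0.6), c(0.1, 0.2))
  expect_equal(heterogeneity_q(h0, 0.3)$Q, 0, tolerance = 1e-12)
  # hand sum: ratios 0.5, 0.25 with ratio SEs 0.1, 0.05 against beta = 0.3
  h1 <- h_of(c(1, 2), rep(0.01, 2), c(0.5, 0.5), c(0.1, 0.1))
  q_hand <- (0.5 - 0.3)^2 / 0.1^2 + (0.25 - 0.3)^2 / 0.05^2
  expect_equal(heterogeneity_q(h1, 0.3)$Q, q_hand, tolerance = 1e-12)
  # null: Q approx chi-square(n-1) in a well-powered regime
  qs <- vapply(1:100, function(i) {
    h <- simulate_summary_stats(50, 0.2, se_exposure_range = c(1e-4, 2e-4),
                                seed = 5000 + i)
    heterogeneity_q(h, ivw(h)$beta)$Q
  }, numeric(1))
  expect_lt(abs(mean(qs) - 49), 3 * sd(qs) / sqrt(length(qs)))
})

test_that("estimators are invariant to joint sign flips of SNP subsets", {
  set.seed(66)
  h <- simulate_summary_stats(40, 0.15, seed = 99)
  flip <- rep(1, 40); flip[c(3, 7, 21)] <- -1
  h2 <- h
  h2$beta_exposure <- h$beta_exposure * flip
  h2$beta_outcome <- h$beta_outcome * flip
  expect_equal(ivw(h2)$beta, ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(h2)$beta, mr_egger(h)$beta, tolerance = 1e-12)
  expect_equal(weighted_median(h2, n_boot = 0)$beta,
               weighted_median(h, n_boot = 0)$beta, tolerance = 1e-12)
})

test_that("estimates agree with literal-formula reference implementations", {
  for (s in 1:10) {
    h <- random_summary(500 + s)
    expect_equal(ivw(h)$beta, ref_ivw(h)$beta, tolerance = 1e-6)
    expect_equal(ivw(h)$se, ref_ivw(h)$se, tolerance = 1e-6)
    e <- mr_egger(h); r <- ref_egger(h)
    expect_equal(e$beta, r$beta, tolerance = 1e-6)
    expect_equal(e$intercept, r$intercept, tolerance = 1e-6)
    expect_equal(weighted_median(h, n_boot = 0)$beta, ref_wm_from_h(h),
                 tolerance = 1e-6)
    expect_equal(penalised_weighted_median(h, n_boot = 0)$beta,
                 ref_pwm_from_h(h), tolerance = 1e-6)
  }
})

test_that("median bootstrap SEs are seeded and reproducible", {
  h <- simulate_summary_stats(30, 0.2, seed = 21)
  e1 <- weighted_median(h, n_boot = 200, seed = 5)
  e2 <- weighted_median(h, n_boot = 200, seed = 5)
  expect_identical(e1$se, e2$se)
  expect_true(is.finite(e1$se) && e1$se > 0)
})

test_that("one-sample 2SLS recovers a direct randomised-exposure estimate", {
  cfg <- sim_config(n_individuals = 8000, n_snps = 30, causal_lnor = -0.25,
                    grs_liability_r2 = 0.2, confounder_effect_exposure = 0,
                    confounder_effect_outcome = 0, seed = 17)
  sim <- simulate_cohort(cfg)
  w <- sim$genotypes$variants_extra[
    , c("variant_id", "effect_allele", "other_allele", "beta")]
  gt <- grs(sim$genotypes, w, qc_prob = NULL)
  est <- one_sample_tsls(gt$grs_s, sim$cohort$morning_person,
                         sim$cohort$depressive_symptoms)
  direct <- fit_logistic(sim$cohort, "depressive_symptoms", "morning_person")
  b_direct <- direct$coefficients$beta[
    direct$coefficients$term == "morning_person"]
  expect_lt(abs(est$beta - b_direct), 3 * est$se)
  expect_gt(est$f_statistic, 10)
  expect_length(est$flags, 0)
  # per-doubling reporting convention
  expect_equal(doubling_or(-0.12)$or, 2^(-0.12))
  expect_equal(round(doubling_or(-0.12)$or, 3), 0.920)
})

test_that("a weak instrument attaches a warning flag", {
  set.seed(3)
  n <- 500
  g_vals <- rnorm(n)
  expos <- rbinom(n, 1, 0.5)            # instrument carries no information
  y <- rbinom(n, 1, 0.2)
  est <- one_sample_tsls(g_vals, expos, y)
  expect_true("weak_instrument" %in% est$flags)
})
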