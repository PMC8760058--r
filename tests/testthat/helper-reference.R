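# Independent reference implementations of the two-sample estimators:
# direct transcriptions of the published formulas, deliberately using a
# different computational route (lm fits, explicit loops) from the package.

ref_ivw <- function(h) {
  w <- 1 / h$se_outcome^2
  fit <- stats::lm(beta_outcome ~ 0 + beta_exposure, data = h, weights = w)
  beta <- unname(coef(fit))
  sigma <- summary(fit)$sigma          # sqrt(Q / (n - 1))
  se_lm <- summary(fit)$coefficients[1, 2]
  se <- if (sigma >= 1) se_lm else se_lm / sigma
  list(beta = beta, se = se)
}

ref_egger <- function(h) {
  flip <- ifelse(h$beta_exposure < 0, -1, 1)
  x <- h$beta_exposure * flip
  y <- h$beta_outcome * flip
  w <- 1 / h$se_outcome^2
  fit <- stats::lm(y ~ x, weights = w)
  sigma <- summary(fit)$sigma          # sqrt(Q / (n - 2))
  co <- summary(fit)$coefficients
  adj <- function(se_lm) if (sigma >= 1) se_lm else se_lm / sigma
  list(beta = unname(co["x", 1]), se = adj(co["x", 2]),
       intercept = unname(co["(Intercept)", 1]),
       intercept_se = adj(co["(Intercept)", 2]))
}

ref_weighted_median <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- weight[ord]
  s <- numeric(length(w))
  acc <- 0
  for (j in seq_along(w)) {
    s[j] <- (acc + w[j] / 2) / sum(w)
    acc <- acc + w[j]
  }
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  below <- max(which(s < 0.5))
  if (any(s == 0.5)) return(r[which(s == 0.5)[1]])
  r[below] + (r[below + 1] - r[below]) * (0.5 - s[below]) /
    (s[below + 1] - s[below])
}

ref_wm_from_h <- function(h) {
  r <- h$beta_outcome / h$beta_exposure
  se_r <- h$se_outcome / abs(h$beta_exposure)
  ref_weighted_median(r, 1 / se_r^2)
}

ref_pwm_from_h <- function(h, penalty = 20) {
  r <- h$beta_outcome / h$beta_exposure
  se_r <- h$se_outcome / abs(h$beta_exposure)
  w <- 1 / se_r^2
  b0 <- ref_weighted_median(r, w)
  qj <- w * (r - b0)^2
  pj <- stats::pchisq(qj, 1, lower.tail = FALSE)
  ref_weighted_median(r, w * pmin(1, penalty * pj))
}

# random aligned summary dataset for agreement checks
random_summary <- function(seed) {
  set.seed(seed)
  n <- sample(5:80, 1)
  h <- data.frame(
    beta_exposure = stats::rnorm(n, 0.06, 0.04),
    se_exposure = stats::runif(n, 0.002, 0.01),
    beta_outcome = stats::rnorm(n, 0, 0.05),
    se_outcome = stats::runif(n, 0.005, 0.05))
  h$beta_exposure[h$beta_exposure == 0] <- 0.01
  class(h) <- c("harmonised_summary", "data.frame")
  h
}
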