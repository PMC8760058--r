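mr_estimate <- function(method, beta, se, n_snps, extra = list()) {
  ci <- wald_ci(beta, se)
  out <- c(list(method = method, beta = beta, se = se,
                ci_low = ci[, "low"], ci_high = ci[, "high"],
                p = wald_p(beta, se), n_snps = n_snps), extra)
  class(out) <- "mr_estimate"
  out
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  size <- if (is.na(x$n_snps)) sprintf("n = %d", x$n) else
    sprintf("%d SNPs", x$n_snps)
  cat(sprintf("%s: beta = %.*f (SE %.*f), 95%% CI [%.*f, %.*f], p = %.3g, %s\n",
              x$method, digits, x$beta, digits, x$se, digits, x$ci_low,
              digits, x$ci_high, x$p, size))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.*f (SE %.*f), p = %.3g\n",
                digits, x$intercept, digits, x$intercept_se, x$intercept_p))
  if (!is.null(x$Q))
    cat(sprintf("  heterogeneity Q = %.2f on %d df (p = %.3g)\n",
                x$Q, x$Q_df, x$Q_p))
  invisible(x)
}

as_harmonised <- function(h) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  stopifnot(all(need %in% names(h)))
  if (any(h$se_exposure <= 0) || any(h$se_outcome <= 0))
    stop("standard errors must be positive")
  h
}

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns per-SNP outcome effects to the exposure's effect allele: swapped
#' effect/other alleles flip the sign of the outcome beta (and complement
#' its EAF); strand differences are resolved by allele complement;
#' palindromic SNPs (A/T or C/G) whose allele frequency is too close to 0.5
#' to resolve the strand are dropped and reported.
#'
#' @param exposure_stats,outcome_stats Data frames with columns
#'   `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`
#'   and optionally `p`, `n`.
#' @param drop_palindromic_maf Palindromic SNPs with minor-allele frequency
#'   above this value (default 0.42, i.e. EAF in (0.42, 0.58)) are treated
#'   as ambiguous and excluded.
#' @return A `harmonised_summary` data frame (`variant_id`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`, `eaf`)
#'   with attribute `dropped` (a data frame of excluded variants and
#'   reasons).
#' @export
harmonise <- function(exposure_stats, outcome_stats,
                      drop_palindromic_maf = 0.42) {
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  stopifnot(all(need %in% names(exposure_stats)),
            all(need %in% names(outcome_stats)))
  m <- match(exposure_stats$variant_id, outcome_stats$variant_id)
  if (all(is.na(m))) stop("no overlapping variants between the two files")

  keep <- !is.na(m)
  ex <- exposure_stats[keep, , drop = FALSE]
  ot <- outcome_stats[m[keep], , drop = FALSE]

  n <- nrow(ex)
  beta_out <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ot$effect_allele[i]; oa_y <- ot$other_allele[i]
    pal <- is_palindromic(ea_x, oa_x)
    if (pal) {
      maf <- min(ex$eaf[i] %||% NA_real_, 1 - (ex$eaf[i] %||% NA_real_))
      if (!is.finite(maf) || maf > drop_palindromic_maf) {
        reason[i] <- "palindromic_ambiguous"
        next
      }
    }
    if (ea_y == ea_x && oa_y == oa_x) {
      beta_out[i] <- ot$beta[i]
    } else if (ea_y == oa_x && oa_y == ea_x) {
      beta_out[i] <- -ot$beta[i]
    } else if (!pal && complement_allele(ea_y) == ea_x &&
               complement_allele(oa_y) == oa_x) {
      beta_out[i] <- ot$beta[i]
    } else if (!pal && complement_allele(ea_y) == oa_x &&
               complement_allele(oa_y) == ea_x) {
      beta_out[i] <- -ot$beta[i]
    } else if (pal && ea_y == ea_x && oa_y == oa_x) {
      beta_out[i] <- ot$beta[i]
    } else {
      reason[i] <- "incompatible_alleles"
    }
  }

  ok <- is.na(reason)
  h <- data.frame(
    variant_id = ex$variant_id[ok],
    beta_exposure = ex$beta[ok], se_exposure = ex$se[ok],
    beta_outcome = beta_out[ok], se_outcome = ot$se[ok],
    eaf = if ("eaf" %in% names(ex)) ex$eaf[ok] else NA_real_,
    stringsAsFactors = FALSE)
  class(h) <- c("harmonised_summary", "data.frame")
  attr(h, "dropped") <- data.frame(
    variant_id = c(exposure_stats$variant_id[!keep], ex$variant_id[!ok]),
    reason = c(rep("absent_from_outcome", sum(!keep)), reason[!ok]),
    stringsAsFactors = FALSE)
  h
}

#' Per-SNP Wald ratio estimates
#'
#' `r_i = beta_outcome_i / beta_exposure_i` with first-order standard error
#' `se_outcome_i / |beta_exposure_i|`. SNPs with a zero exposure effect are
#' excluded with a reason.
#'
#' @param h A `harmonised_summary`.
#' @return `data.frame` with `variant_id`, `ratio`, `se`, `weight`
#'   (inverse-variance `1/se^2`).
#' @export
ratio_estimates <- function(h) {
  h <- as_harmonised(h)
  nonzero <- h$beta_exposure != 0
  if (!any(nonzero)) stop("all exposure effects are zero")
  h <- h[nonzero, , drop = FALSE]
  r <- h$beta_outcome / h$beta_exposure
  se <- h$se_outcome / abs(h$beta_exposure)
  ids <- h$variant_id %||% sprintf("snp%04d", seq_len(nrow(h)))
  data.frame(variant_id = ids, ratio = r, se = se,
             weight = 1 / se^2, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted estimator (multiplicative random effects)
#'
#' Weighted regression of the per-SNP outcome effects on the exposure
#' effects with the intercept constrained to zero and weights
#' `1 / se_outcome^2`. Under the multiplicative random-effects model the
#' standard error is inflated by `max(1, sqrt(Q / (n - 1)))`, which accounts
#' for balanced horizontal pleiotropy without changing the point estimate.
#'
#' @param h A `harmonised_summary`.
#' @return An `mr_estimate` with heterogeneity `Q`, `Q_df`, `Q_p`. With a
#'   single SNP the Wald ratio is returned with a fixed-effect caveat flag.
#' @export
ivw <- function(h) {
  h <- as_harmonised(h)
  n <- nrow(h)
  if (n < 1) stop("no SNPs")
  w <- 1 / h$se_outcome^2
  x <- h$beta_exposure; y <- h$beta_outcome
  beta <- sum(w * x * y) / sum(w * x^2)
  se_fixed <- sqrt(1 / sum(w * x^2))
  if (n == 1) {
    est <- mr_estimate("ivw", beta, se_fixed, 1,
                       list(flag = "single_snp_fixed_effect"))
    return(est)
  }
  q <- sum(w * (y - beta * x)^2)
  scale <- max(1, sqrt(q / (n - 1)))
  mr_estimate("ivw", beta, se_fixed * scale, n,
              list(Q = q, Q_df = n - 1L,
                   Q_p = stats::pchisq(q, n - 1, lower.tail = FALSE)))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept: the slope is the causal estimate and the intercept the average
#' directional pleiotropy (valid under the InSIDE assumption that
#' pleiotropic effects are independent of the variant-exposure effects).
#' Exposure effects are first oriented positive, which the intercept
#' requires for identifiability. Standard errors use the same multiplicative
#' random-effects inflation as [ivw()] with `n - 2` degrees of freedom.
#'
#' @param h A `harmonised_summary` with at least 3 SNPs.
#' @return An `mr_estimate` with `intercept`, `intercept_se`, `intercept_p`
#'   and heterogeneity statistics.
#' @export
mr_egger <- function(h) {
  h <- as_harmonised(h)
  n <- nrow(h)
  if (n < 3) stop("MR-Egger requires at least 3 SNPs")
  flip <- sign(h$beta_exposure)
  flip[flip == 0] <- 1
  x <- h$beta_exposure * flip
  y <- h$beta_outcome * flip
  w <- 1 / h$se_outcome^2

  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  sxx <- sum(w * x^2) - swx^2 / sw
  sxy <- sum(w * x * y) - swx * swy / sw
  beta <- sxy / sxx
  alpha <- (swy - beta * swx) / sw
  resid <- y - alpha - beta * x
  q <- sum(w * resid^2)
  scale <- max(1, sqrt(q / (n - 2)))
  se_beta <- sqrt(1 / sxx) * scale
  se_alpha <- sqrt(1 / sw + (swx / sw)^2 / sxx) * scale

  mr_estimate("egger", beta, se_beta, n,
              list(intercept = alpha, intercept_se = se_alpha,
                   intercept_p = wald_p(alpha, se_alpha),
                   Q = q, Q_df = n - 2L,
                   Q_p = stats::pchisq(q, n - 2, lower.tail = FALSE)))
}

weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

median_bootstrap_se <- function(h, n_boot, seed, point_fun) {
  if (n_boot <= 0) return(NA_real_)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(h)
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(n, h$beta_exposure, h$se_exposure)
    by <- stats::rnorm(n, h$beta_outcome, h$se_outcome)
    bx[bx == 0] <- .Machine$double.eps
    r <- by / bx
    w <- (abs(bx) / h$se_outcome)^2
    point_fun(r, w)
  }, numeric(1))
  stats::sd(boots)
}

#' Weighted median estimator
#'
#' The causal estimate is the weighted median of the per-SNP Wald ratios:
#' with standardised cumulative inverse-variance weights
#' `s_j = (sum_(k<=j) w_k - w_j / 2) / sum(w)` over the sorted ratios, the
#' estimate interpolates the ratio at `s = 0.5`. Consistent when at least
#' half the weight comes from valid instruments, without the InSIDE
#' assumption. The standard error is a seeded parametric bootstrap over
#' per-SNP normal draws.
#'
#' @param h A `harmonised_summary` with at least 3 SNPs.
#' @param n_boot Bootstrap replicates for the SE (0 skips it).
#' @param seed Seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  h <- as_harmonised(h)
  if (nrow(h) < 3) stop("weighted median requires at least 3 SNPs")
  re <- ratio_estimates(h)
  beta <- weighted_median_point(re$ratio, re$weight)
  se <- median_bootstrap_se(h, n_boot, seed, weighted_median_point)
  mr_estimate("wmedian", beta, se, nrow(h))
}

penalised_weights <- function(r, w, beta_wm, penalty) {
  qj <- w * (r - beta_wm)^2
  pj <- stats::pchisq(qj, df = 1, lower.tail = FALSE)
  w * pmin(1, penalty * pj)
}

#' Penalised weighted median estimator
#'
#' Downweights outlying variants before taking the weighted median: each
#' SNP's one-degree-of-freedom heterogeneity statistic against the plain
#' weighted-median estimate, `Q_j = w_j (r_j - beta_wm)^2`, yields an
#' upper-tail chi-square p value `p_j`, and the penalised weights are
#' `w_j * min(1, penalty * p_j)`. With no outliers (all `p_j` above
#' `1 / penalty`) the estimator equals the plain weighted median.
#'
#' @inheritParams weighted_median
#' @param penalty Penalisation constant (default 20).
#' @return An `mr_estimate`.
#' @export
penalised_weighted_median <- function(h, penalty = 20, n_boot = 1000,
                                      seed = NULL) {
  h <- as_harmonised(h)
  if (nrow(h) < 3) stop("penalised weighted median requires at least 3 SNPs")
  re <- ratio_estimates(h)
  beta_wm <- weighted_median_point(re$ratio, re$weight)
  w_pen <- penalised_weights(re$ratio, re$weight, beta_wm, penalty)
  beta <- weighted_median_point(re$ratio, w_pen)
  se <- median_bootstrap_se(h, n_boot, seed, function(r, w) {
    b0 <- weighted_median_point(r, w)
    weighted_median_point(r, penalised_weights(r, w, b0, penalty))
  })
  mr_estimate("pwmedian", beta, se, nrow(h))
}

#' Cochran heterogeneity statistic for the Wald ratios
#'
#' `Q = sum_i w_i (r_i - beta)^2` with inverse-variance weights on the
#' first-order ratio SEs; under valid instruments Q is approximately
#' chi-square with `n - 1` degrees of freedom.
#'
#' @param h A `harmonised_summary` with at least 2 SNPs.
#' @param beta The causal estimate the ratios are compared against.
#' @return A list with `Q`, `df`, `p`.
#' @export
heterogeneity_q <- function(h, beta) {
  h <- as_harmonised(h)
  if (nrow(h) < 2) stop("heterogeneity requires at least 2 SNPs")
  re <- ratio_estimates(h)
  q <- sum(re$weight * (re$ratio - beta)^2)
  df <- nrow(re) - 1L
  list(Q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Run all two-sample estimators
#'
#' @param h A `harmonised_summary`.
#' @param methods Subset of `c("ivw", "egger", "wmedian", "pwmedian")`.
#' @param n_boot,seed Bootstrap controls for the median estimators.
#' @return Named list of `mr_estimate` objects.
#' @export
mr_twosample <- function(h, methods = c("ivw", "egger", "wmedian", "pwmedian"),
                         n_boot = 1000, seed = NULL) {
  fits <- list()
  if ("ivw" %in% methods) fits$ivw <- ivw(h)
  if ("egger" %in% methods) fits$egger <- mr_egger(h)
  if ("wmedian" %in% methods)
    fits$wmedian <- weighted_median(h, n_boot = n_boot, seed = seed)
  if ("pwmedian" %in% methods)
    fits$pwmedian <- penalised_weighted_median(h, n_boot = n_boot, seed = seed)
  fits
}

#' One-sample Mendelian randomisation (two-stage least squares)
#'
#' Stage 1 regresses the binary exposure linearly on the standardised
#' genetic risk score (plus covariates) and retains the fitted values as
#' predicted morningness; stage 2 regresses the mental-health outcome on the
#' fitted exposure (plus the same covariates) by logistic regression for a
#' binary outcome or proportional-odds regression for an ordinal one. The
#' reported beta is the stage-2 coefficient on the fitted exposure (log-odds
#' scale); rescale with [doubling_or()] for the per-doubling convention. A
#' first-stage F statistic below `weak_f` attaches a weak-instrument
#' warning flag. An optional nonparametric bootstrap resamples participants
#' through both stages.
#'
#' @param grs Numeric genetic risk score vector.
#' @param exposure Binary (0/1) exposure vector.
#' @param outcome Binary or ordinal outcome vector.
#' @param covariates Optional `data.frame` of covariates entering both
#'   stages.
#' @param stage1 `"linear"` (default) or `"logistic"` first stage.
#' @param weak_f First-stage F threshold for the weak-instrument flag.
#' @param n_boot Nonparametric bootstrap replicates for an alternative SE
#'   (0 skips).
#' @param seed Bootstrap seed.
#' @return An `mr_estimate` (method `"tsls"`) with `f_statistic`,
#'   optional `boot_se`, and flags.
#' @export
one_sample_tsls <- function(grs, exposure, outcome, covariates = NULL,
                            stage1 = c("linear", "logistic"),
                            weak_f = 10, n_boot = 0, seed = NULL) {
  stage1 <- match.arg(stage1)
  stopifnot(length(grs) == length(exposure), length(grs) == length(outcome))
  d <- data.frame(.grs = grs, .exposure = exposure)
  if (!is.null(covariates)) d <- cbind(d, covariates)
  cov_names <- setdiff(names(d), c(".grs", ".exposure"))
  d$.outcome <- outcome
  d <- d[stats::complete.cases(d), , drop = FALSE]

  fit_stages <- function(d) {
    f1 <- make_formula(".exposure", ".grs", cov_names)
    s1 <- if (stage1 == "linear") stats::lm(f1, data = d)
          else stats::glm(f1, data = d, family = stats::binomial())
    d$.fitted <- as.numeric(stats::fitted(s1))
    if (stats::var(d$.fitted) == 0) stop("constant fitted exposure")
    binary <- length(unique(d$.outcome)) == 2
    if (binary) {
      s2 <- suppressWarnings(
        stats::glm(make_formula(".outcome", ".fitted", cov_names),
                   data = d, family = stats::binomial()))
      beta <- stats::coef(s2)[[".fitted"]]
      se <- sqrt(stats::vcov(s2)[".fitted", ".fitted"])
    } else {
      d$.outcome <- factor(d$.outcome, ordered = TRUE)
      s2 <- polr_fit(make_formula(".outcome", ".fitted", cov_names), d)
      beta <- stats::coef(s2)[[".fitted"]]
      se <- sqrt(stats::vcov(s2)[".fitted", ".fitted"])
    }
    list(beta = beta, se = se, s1 = s1)
  }

  fit <- fit_stages(d)
  fstat <- if (stage1 == "linear") summary(fit$s1)$fstatistic[["value"]] else {
    summary(stats::lm(make_formula(".exposure", ".grs", cov_names),
                      data = d))$fstatistic[["value"]]
  }
  flags <- if (fstat < weak_f) "weak_instrument" else character(0)

  boot_se <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(d), replace = TRUE)
      tryCatch(fit_stages(d[idx, , drop = FALSE])$beta,
               error = function(e) NA_real_)
    }, numeric(1))
    boot_se <- stats::sd(boots, na.rm = TRUE)
  }

  mr_estimate("tsls", fit$beta, fit$se, NA_integer_,
              list(f_statistic = fstat, boot_se = boot_se, n = nrow(d),
                   flags = flags))
}
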