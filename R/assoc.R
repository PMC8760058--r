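# MASS::polr with a deterministic fallback start (zero slopes, cutpoints at
# the empirical cumulative log-odds) for sparse high-category outcomes where
# the default initialisation is non-finite
polr_fit <- function(formula, data) {
  fit <- tryCatch(
    suppressWarnings(MASS::polr(formula, data = data, method = "logistic",
                                Hess = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit)) return(fit)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  p <- ncol(stats::model.matrix(formula, mf)) - 1L
  cum <- cumsum(prop.table(table(y)))
  zeta0 <- stats::qlogis(pmin(pmax(cum[-length(cum)], 1e-4), 1 - 1e-4))
  suppressWarnings(MASS::polr(formula, data = data, method = "logistic",
                              Hess = TRUE, start = c(rep(0, p), zeta0),
                              control = list(maxit = 200)))
}

make_formula <- function(outcome, predictors, covariates) {
  rhs <- paste(c(predictors, covariates), collapse = " + ")
  stats::as.formula(paste0("`", outcome, "` ~ ", rhs))
}

fit_result <- function(terms, beta, se, n, loglik, family, flags = character(0)) {
  ci <- wald_ci(beta, se)
  out <- list(
    coefficients = data.frame(
      term = terms, beta = beta, se = se, or = exp(beta),
      ci_low = exp(ci[, "low"]), ci_high = exp(ci[, "high"]),
      p = wald_p(beta, se), stringsAsFactors = FALSE),
    n = n, loglik = loglik, family = family, flags = flags)
  class(out) <- "chronomr_fit"
  out
}

#' @export
print.chronomr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s model, n = %d, logLik = %.2f\n", x$family, x$n, x$loglik))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Logistic regression for binary mental-health outcomes
#'
#' Maximum-likelihood logistic fit of a binary outcome on the exposure and
#' covariates, reporting odds ratios with Wald 95% confidence intervals.
#' Rows with missing values in any model variable are dropped (complete-case
#' analysis) and the exclusion count is recorded. Quasi-separation (any
#' coefficient with an extreme estimate or standard error, or
#' non-convergence) is flagged rather than silently returned.
#'
#' @param data `data.frame` holding all model variables.
#' @param outcome Name of the binary (0/1) outcome column.
#' @param predictors Character vector of predictor column names.
#' @param covariates Character vector of adjustment column names.
#' @return A `chronomr_fit` with a per-term coefficient table
#'   (`term`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `p`), `n`, log
#'   likelihood and flags. The attribute `n_dropped` counts excluded rows.
#' @export
fit_logistic <- function(data, outcome, predictors, covariates = character(0)) {
  vars <- c(outcome, predictors, covariates)
  stopifnot(all(vars %in% names(data)))
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, vars, drop = FALSE]
  y <- d[[outcome]]
  if (length(unique(y)) < 2) stop("outcome has a single class")

  # separation and non-convergence are detected below and surfaced as
  # flags, so glm.fit's own warnings are redundant here
  fit <- suppressWarnings(
    stats::glm(make_formula(outcome, predictors, covariates),
               data = d, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 50)))
  sm <- summary(fit)$coefficients
  # Wald SEs from the observed information at the final MLE (summary.glm
  # reuses the IRLS weights of the penultimate step, which is ~1e-7 off)
  X <- stats::model.matrix(fit)[, !is.na(stats::coef(fit)), drop = FALSE]
  pr <- stats::fitted(fit)
  info_se <- tryCatch(
    sqrt(diag(chol2inv(chol(crossprod(X * sqrt(pr * (1 - pr))))))),
    error = function(e) NULL)
  if (!is.null(info_se) && length(info_se) == nrow(sm))
    sm[, "Std. Error"] <- info_se
  flags <- character(0)
  if (!fit$converged) flags <- c(flags, "non_convergence")
  if (any(abs(sm[, "Estimate"]) > 15) || any(sm[, "Std. Error"] > 100))
    flags <- c(flags, "possible_separation")
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) flags <- c(flags, "collinear_columns_dropped")

  res <- fit_result(rownames(sm), sm[, "Estimate"], sm[, "Std. Error"],
                    n = nrow(d), loglik = as.numeric(stats::logLik(fit)),
                    family = "logistic", flags = flags)
  attr(res, "n_dropped") <- sum(!cc)
  res
}

#' Proportional-odds ordinal regression for severity scores
#'
#' Fits a proportional-odds (ordered logistic) model via maximum likelihood:
#' shared slope vector plus ordered cutpoints. Slopes are reported on the
#' same log-odds scale as [fit_logistic()] (positive slope = higher
#' categories more likely); with two categories the slope reduces exactly to
#' the binary logistic slope.
#'
#' @inheritParams fit_logistic
#' @param outcome Name of an ordinal column (integer scores or ordered
#'   factor; at least 2 observed categories).
#' @return A `chronomr_fit`; the cutpoint estimates are kept in the
#'   `zeta` attribute.
#' @export
fit_ordinal <- function(data, outcome, predictors, covariates = character(0)) {
  vars <- c(outcome, predictors, covariates)
  stopifnot(all(vars %in% names(data)))
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, vars, drop = FALSE]
  y <- d[[outcome]]
  if (!is.ordered(y)) y <- factor(y, ordered = TRUE)
  if (nlevels(droplevels(y)) < 2) stop("need >= 2 observed categories")
  d[[outcome]] <- droplevels(y)

  if (nlevels(d[[outcome]]) == 2) {
    # the proportional-odds model with one cutpoint IS binary logistic
    d[[outcome]] <- as.integer(d[[outcome]]) - 1L
    res <- fit_logistic(d, outcome, predictors, covariates)
    res$family <- "ordinal"
    attr(res, "n_dropped") <- sum(!cc)
    return(res)
  }

  fit <- polr_fit(make_formula(outcome, predictors, covariates), d)
  flags <- if (fit$convergence != 0) "non_convergence" else character(0)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(vc)) {
    flags <- c(flags, "hessian_failure")
    se <- rep(NA_real_, length(stats::coef(fit)))
  } else {
    se <- sqrt(diag(vc))[seq_along(stats::coef(fit))]
  }
  res <- fit_result(names(stats::coef(fit)), as.numeric(stats::coef(fit)), se,
                    n = nrow(d), loglik = as.numeric(stats::logLik(fit)),
                    family = "ordinal", flags = flags)
  attr(res, "n_dropped") <- sum(!cc)
  attr(res, "zeta") <- fit$zeta
  res
}

#' Odds ratio per doubling of genetic liability
#'
#' A genetic association estimated on the log-odds exposure scale is
#' rescaled to the change per twofold increase in genetic liability:
#' `OR = exp(beta * ln 2) = 2^beta`, with confidence limits transformed
#' identically.
#'
#' @param beta Log odds ratio per unit of the exposure (log-odds scale).
#' @param se Optional standard error for the confidence interval.
#' @param conf Confidence level (default 0.95).
#' @return A list with `or` and, when `se` is given, `ci_low`/`ci_high`.
#' @export
#' @examples
#' doubling_or(-0.12)$or   # 0.920
doubling_or <- function(beta, se = NULL, conf = 0.95) {
  stopifnot(is.finite(beta))
  out <- list(or = 2^beta)
  if (!is.null(se)) {
    ci <- wald_ci(beta, se, conf)
    out$ci_low <- 2^ci[, "low"]
    out$ci_high <- 2^ci[, "high"]
  }
  out
}

#' Fisher's z test for a sex difference in effect size
#'
#' `z = (beta_m - beta_f) / sqrt(se_m^2 + se_f^2)` with a two-sided normal
#' p value; used to compare male- and female-stratum estimates of the same
#' effect.
#'
#' @param beta_m,se_m Male-stratum estimate and standard error.
#' @param beta_f,se_f Female-stratum estimate and standard error.
#' @return A list with `beta_m`, `se_m`, `beta_f`, `se_f`, `z`, `p`.
#' @export
#' @examples
#' fishers_z(0.3, 0.1, 0.1, 0.1)$z   # 1.4142
fishers_z <- function(beta_m, se_m, beta_f, se_f) {
  if (any(c(se_m, se_f) <= 0)) stop("standard errors must be positive")
  z <- (beta_m - beta_f) / sqrt(se_m^2 + se_f^2)
  list(beta_m = beta_m, se_m = se_m, beta_f = beta_f, se_f = se_f,
       z = z, p = 2 * stats::pnorm(-abs(z)))
}
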