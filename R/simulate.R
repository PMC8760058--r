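#' Simulate genotype dosages at independent biallelic SNPs
#'
#' Draws per-SNP allele frequencies uniformly from `config$maf_range` and
#' dosages as two Bernoulli allele draws (Hardy-Weinberg). Instrument SNPs
#' are simulated without linkage disequilibrium, matching the GWAS-pruned
#' independent hits used as chronotype instruments. Each variant carries a
#' true positive per-allele weight on the morningness liability.
#'
#' @param config A [sim_config()].
#' @param variants Optional variant table from a previous call; when given,
#'   its allele frequencies and weights are reused so that a second cohort
#'   (e.g. the outcome sample of a two-sample design) shares the same
#'   instruments.
#' @param seed Optional seed override (defaults to a stream derived from
#'   `config$seed`).
#' @return A [genotype_matrix()] whose variant table has columns
#'   `variant_id`, `effect_allele`, `other_allele`, `maf` and `beta` (the
#'   true morningness weight).
#' @export
simulate_genotypes <- function(config, variants = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed %||% sub_seed(config$seed, 11L))
  n <- config$n_individuals
  L <- config$n_snps

  if (is.null(variants)) {
    maf <- stats::runif(L, config$maf_range[1], config$maf_range[2])
    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, L, replace = TRUE)
    # exclude the complement so simulated instruments are never palindromic
    oa <- vapply(ea, function(a) sample(setdiff(bases, c(a, .complement[[a]])), 1L),
                 character(1))
    variants <- data.frame(
      variant_id = sprintf("rs%05d", seq_len(L)),
      effect_allele = ea,
      other_allele = unname(oa),
      maf = maf,
      beta = stats::runif(L, 0.02, 0.12),
      stringsAsFactors = FALSE
    )
  } else {
    stopifnot(nrow(variants) == L)
  }

  dosages <- vapply(variants$maf,
                    function(p) stats::rbinom(n, 2L, p),
                    integer(n))
  dosages <- matrix(as.numeric(dosages), nrow = n, ncol = L,
                    dimnames = list(sprintf("id%06d", seq_len(n)),
                                    variants$variant_id))
  genotype_matrix(dosages,
                  variants[, c("variant_id", "effect_allele", "other_allele")],
                  variants_extra = variants)
}

#' Simulate the morning-person exposure and baseline covariates
#'
#' Builds a liability for morningness as `a * GRS + b * confounder + noise`,
#' with `a` solved so the true genetic score explains exactly
#' `grs_liability_r2` of the liability variance, then dichotomises at the
#' quantile giving `case_fraction` morning people. Demographic covariates
#' (sex, age, assessment centre, deprivation, BMI, smoking, shift work,
#' medication and sleep-disturbance flags) are drawn with marginals chosen
#' to resemble a middle-aged population cohort.
#'
#' @param genotypes A [genotype_matrix()] from [simulate_genotypes()].
#' @param config A [sim_config()].
#' @param seed Optional seed override.
#' @return A `data.frame` cohort with one row per participant and an attached
#'   `truth` attribute (scaling coefficients and the true genetic score) for
#'   test assertions; real data simply lack this attribute.
#' @export
simulate_exposure <- function(genotypes, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "genotype_matrix"))
  r2 <- config$grs_liability_r2
  if (r2 < 0 || r2 >= 1) stop_config("grs_liability_r2", "must lie in [0, 1)")
  set.seed(seed %||% sub_seed(config$seed, 23L))

  n <- nrow(genotypes$dosages)
  beta <- genotypes$variants_extra$beta
  g <- drop(genotypes$dosages %*% beta)
  confounder <- stats::rnorm(n)
  b <- config$confounder_effect_exposure
  var_g <- stats::var(g)
  a <- if (r2 == 0 || var_g == 0) 0 else sqrt(r2 * (b^2 + 1) / ((1 - r2) * var_g))
  liability <- a * g + b * confounder + stats::rnorm(n)
  threshold <- stats::quantile(liability, 1 - config$case_fraction, names = FALSE)
  morning <- as.integer(liability > threshold)

  cohort <- data.frame(
    participant_id = rownames(genotypes$dosages),
    morning_person = morning,
    liability = liability,
    confounder = confounder,
    sex = stats::rbinom(n, 1L, 0.44),            # 1 = male
    age = round(stats::runif(n, 40, 70)),
    centre = factor(sample(sprintf("centre%02d", 1:22), n, replace = TRUE)),
    tdi = stats::rnorm(n, -1.45, 3),
    bmi = stats::rnorm(n, 27.4, 4.8),
    smoking = factor(sample(c("never", "former", "current"), n, replace = TRUE,
                            prob = c(0.54, 0.355, 0.105)),
                     levels = c("never", "former", "current")),
    shift_worker = stats::rbinom(n, 1L, 0.10),
    on_relevant_medication = stats::rbinom(n, 1L, 0.15),
    sleep_disturbed = stats::rbinom(n, 1L, 0.25),
    stringsAsFactors = FALSE
  )
  if (config$missing_rate > 0) {
    for (col in c("tdi", "bmi", "smoking")) {
      drop_idx <- stats::runif(n) < config$missing_rate
      cohort[[col]][drop_idx] <- NA
    }
  }
  attr(cohort, "truth") <- list(grs_scale = a, confounder_scale = b,
                                grs_true = g, threshold = threshold)
  cohort
}

# fixed proportional-odds cutpoints: qlogis of the cumulative baseline
# category probabilities, so lp = 0 reproduces the documented marginals
ordinal_cutpoints <- function(values, base_prob) {
  p <- base_prob / sum(base_prob)
  stats::qlogis(cumsum(p[-length(p)]))
}

# default baseline score distributions (geometric-style decay for symptom
# scores, a centred bell for wellbeing); chosen to give means near the
# descriptive statistics of large population cohorts
.ordinal_defaults <- list(
  phq9_severity = list(values = 0:27, base = exp(-0.33 * (0:27))),
  gad_severity = list(values = 0:21, base = exp(-0.40 * (0:21))),
  cidi_severity = list(values = 0:15, base = exp(-0.30 * (0:15))),
  wellbeing_score = list(values = 3:17,
                         base = stats::dnorm(3:17, mean = 12.6, sd = 2))
)

r_prop_odds <- function(lp, values, base_prob) {
  cuts <- ordinal_cutpoints(values, base_prob)
  latent <- lp + stats::rlogis(length(lp))
  values[findInterval(latent, cuts) + 1L]
}

solve_intercept <- function(lp, prevalence) {
  f <- function(alpha) mean(stats::plogis(alpha + lp)) - prevalence
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

draw_pleiotropy <- function(beta, config) {
  L <- length(beta)
  gamma <- numeric(L)
  n_invalid <- round(config$invalid_fraction * L)
  if (n_invalid == 0 || config$pleiotropy_mode == "none") {
    attr(gamma, "invalid_idx") <- integer(0)
    return(gamma)
  }
  idx <- sample.int(L, n_invalid)
  s <- config$pleiotropy_sd
  gamma[idx] <- switch(config$pleiotropy_mode,
    balanced = stats::rnorm(n_invalid, 0, s),
    directional = abs(stats::rnorm(n_invalid, 0, s)),
    inside_violating = s * (beta[idx] - mean(beta)) / stats::sd(beta) +
      stats::rnorm(n_invalid, 0, s / 2)
  )
  attr(gamma, "invalid_idx") <- idx
  gamma
}

#' Simulate mental-health outcomes downstream of diurnal preference
#'
#' Binary outcomes follow a logistic model
#' `logit p = alpha + causal_lnor * morning_person +
#'  confounder_effect_outcome * confounder + sum_j gamma_j d_j`,
#' where the pleiotropic effects `gamma_j` are nonzero for the configured
#' fraction of invalid SNPs, and the intercept is solved numerically so the
#' marginal case rate matches the target prevalence. Ordinal severity scores
#' follow a proportional-odds latent-variable model with the same linear
#' predictor and fixed documented cutpoints. The wellbeing score receives
#' the negated predictor (higher wellbeing is the beneficial direction).
#'
#' @param cohort Cohort from [simulate_exposure()].
#' @param genotypes The matching [genotype_matrix()].
#' @param config A [sim_config()].
#' @param seed Optional seed override.
#' @return The cohort with outcome columns filled
#'   (`depressive_symptoms`, `major_depression`, `gad` binary;
#'   `phq9_severity`, `gad_severity`, `cidi_severity`, `wellbeing_score`
#'   ordinal) and the `truth` attribute extended with the pleiotropy vector
#'   `gamma` and the solved intercepts.
#' @export
simulate_outcomes <- function(cohort, genotypes, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"),
            all(c("morning_person", "confounder") %in% names(cohort)))
  prev <- config$outcome_prevalence
  if (prev <= 0 || prev >= 1)
    stop_config("outcome_prevalence", "must lie strictly in (0, 1)")
  set.seed(seed %||% sub_seed(config$seed, 37L))

  beta <- genotypes$variants_extra$beta
  gamma <- draw_pleiotropy(beta, config)
  direct <- drop(genotypes$dosages %*% gamma)
  lp <- config$causal_lnor * cohort$morning_person +
    config$confounder_effect_outcome * cohort$confounder + direct

  prevalences <- c(depressive_symptoms = prev, major_depression = 0.08,
                   gad = 0.016)
  alphas <- numeric(0)
  for (nm in names(prevalences)) {
    alpha <- solve_intercept(lp, prevalences[[nm]])
    cohort[[nm]] <- stats::rbinom(nrow(cohort), 1L, stats::plogis(alpha + lp))
    alphas[nm] <- alpha
  }
  for (nm in names(.ordinal_defaults)) {
    spec <- .ordinal_defaults[[nm]]
    lp_nm <- if (nm == "wellbeing_score") -lp else lp
    cohort[[nm]] <- r_prop_odds(lp_nm, spec$values, spec$base)
  }

  truth <- attr(cohort, "truth") %||% list()
  truth$gamma <- as.numeric(gamma)
  truth$invalid_idx <- attr(gamma, "invalid_idx")
  truth$alphas <- alphas
  attr(cohort, "truth") <- truth
  cohort
}

#' Simulate a full individual-level cohort
#'
#' Convenience wrapper running [simulate_genotypes()], [simulate_exposure()]
#' and [simulate_outcomes()] in sequence.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `cohort` (a `data.frame` with the `truth` attribute).
#' @export
simulate_cohort <- function(config) {
  genotypes <- simulate_genotypes(config)
  cohort <- simulate_exposure(genotypes, config)
  cohort <- simulate_outcomes(cohort, genotypes, config)
  list(genotypes = genotypes, cohort = cohort)
}

# per-SNP simple linear regression of y on each dosage column, closed form
snp_linear_scan <- function(dosages, y) {
  n <- length(y)
  xc <- scale(dosages, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- drop(crossprod(xc, yc))
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss <- sum(yc^2) - ifelse(sxx > 0, beta^2 * sxx, 0)
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  data.frame(beta = beta, se = se, p = wald_p(beta, se))
}

# per-SNP univariable logistic regression (intercept + dosage)
snp_logistic_scan <- function(dosages, y) {
  L <- ncol(dosages)
  beta <- se <- rep(NA_real_, L)
  for (j in seq_len(L)) {
    x <- cbind(1, dosages[, j])
    fit <- suppressWarnings(
      stats::glm.fit(x, y, family = stats::binomial()))
    cov <- tryCatch(chol2inv(chol(crossprod(x * sqrt(fit$weights)))),
                    error = function(e) NULL)
    if (!is.null(cov)) {
      beta[j] <- fit$coefficients[2]
      se[j] <- sqrt(cov[2, 2])
    }
  }
  data.frame(beta = beta, se = se, p = wald_p(beta, se))
}

#' Simulate two-sample GWAS summary statistics from disjoint cohorts
#'
#' Simulates two independent cohorts sharing the same instrument SNPs: in the
#' exposure sample each SNP is regressed linearly on the continuous
#' morningness liability; in the outcome sample each SNP enters a
#' univariable logistic regression on the binary outcome. A configurable
#' fraction of outcome-side records is reported on the swapped allele
#' (beta negated, EAF complemented) to exercise harmonisation.
#'
#' @param config A [sim_config()] (`flip_fraction` controls allele swaps).
#' @param outcome Name of the binary outcome used on the outcome side.
#' @return A list of class `summary_stats_pair` with `exposure` and
#'   `outcome` data frames (columns `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `p`, `n`) and attribute
#'   `flipped_ids`.
#' @export
make_two_sample_stats <- function(config, outcome = "depressive_symptoms") {
  stopifnot(inherits(config, "sim_config"))

  g1 <- simulate_genotypes(config)
  c1 <- simulate_exposure(g1, config)
  exp_scan <- snp_linear_scan(g1$dosages, c1$liability)

  g2 <- simulate_genotypes(config, variants = g1$variants_extra,
                           seed = sub_seed(config$seed, 101L))
  c2 <- simulate_exposure(g2, config, seed = sub_seed(config$seed, 103L))
  c2 <- simulate_outcomes(c2, g2, config, seed = sub_seed(config$seed, 107L))
  out_scan <- snp_logistic_scan(g2$dosages, c2[[outcome]])

  v <- g1$variants_extra
  exposure <- data.frame(
    variant_id = v$variant_id, effect_allele = v$effect_allele,
    other_allele = v$other_allele, eaf = colMeans(g1$dosages) / 2,
    beta = exp_scan$beta, se = exp_scan$se, p = exp_scan$p,
    n = nrow(g1$dosages), stringsAsFactors = FALSE)
  outcome_df <- data.frame(
    variant_id = v$variant_id, effect_allele = v$effect_allele,
    other_allele = v$other_allele, eaf = colMeans(g2$dosages) / 2,
    beta = out_scan$beta, se = out_scan$se, p = out_scan$p,
    n = nrow(g2$dosages), stringsAsFactors = FALSE)

  flipped <- character(0)
  if (config$flip_fraction > 0) {
    set.seed(sub_seed(config$seed, 113L))
    n_flip <- round(config$flip_fraction * nrow(outcome_df))
    idx <- sample.int(nrow(outcome_df), n_flip)
    flipped <- outcome_df$variant_id[idx]
    ea <- outcome_df$effect_allele[idx]
    outcome_df$effect_allele[idx] <- outcome_df$other_allele[idx]
    outcome_df$other_allele[idx] <- ea
    outcome_df$beta[idx] <- -outcome_df$beta[idx]
    outcome_df$eaf[idx] <- 1 - outcome_df$eaf[idx]
  }

  structure(list(exposure = exposure, outcome = outcome_df),
            flipped_ids = flipped, class = "summary_stats_pair")
}

#' Simulate summary statistics directly at the summary level
#'
#' Fast generator used for estimator calibration studies: per-SNP true
#' exposure effects are drawn positive, estimated effects add normal noise at
#' the stated standard errors, and outcome effects are
#' `true_effect * beta_true + gamma` with pleiotropy per the configured mode.
#' Returns data already aligned (no allele bookkeeping), ready for the
#' two-sample estimators.
#'
#' @param n_snps Number of instruments.
#' @param true_effect True causal slope.
#' @param pleiotropy_mode,invalid_fraction,pleiotropy_sd As in [sim_config()].
#' @param se_exposure_range,se_outcome_range Uniform ranges for per-SNP
#'   standard errors.
#' @param seed Integer seed.
#' @return A `harmonised_summary` data frame with a `truth` attribute
#'   (true per-SNP effects and the pleiotropy vector).
#' @export
simulate_summary_stats <- function(n_snps = 100,
                                   true_effect = 0,
                                   pleiotropy_mode = c("none", "balanced",
                                                       "directional",
                                                       "inside_violating"),
                                   invalid_fraction = 0,
                                   pleiotropy_sd = 0.05,
                                   se_exposure_range = c(0.002, 0.006),
                                   se_outcome_range = c(0.01, 0.04),
                                   seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  set.seed(seed)
  beta_true <- stats::runif(n_snps, 0.02, 0.12)
  se_x <- stats::runif(n_snps, se_exposure_range[1], se_exposure_range[2])
  se_y <- stats::runif(n_snps, se_outcome_range[1], se_outcome_range[2])
  cfg <- list(invalid_fraction = invalid_fraction,
              pleiotropy_mode = pleiotropy_mode,
              pleiotropy_sd = pleiotropy_sd)
  gamma <- draw_pleiotropy(beta_true, cfg)
  h <- data.frame(
    variant_id = sprintf("rs%05d", seq_len(n_snps)),
    beta_exposure = beta_true + stats::rnorm(n_snps, 0, se_x),
    se_exposure = se_x,
    beta_outcome = true_effect * beta_true + as.numeric(gamma) +
      stats::rnorm(n_snps, 0, se_y),
    se_outcome = se_y,
    stringsAsFactors = FALSE
  )
  class(h) <- c("harmonised_summary", "data.frame")
  attr(h, "truth") <- list(beta_true = beta_true, gamma = as.numeric(gamma),
                           invalid_idx = attr(gamma, "invalid_idx"))
  h
}

#' Simulate per-night actigraphy sleep episodes
#'
#' Generates `n_nights` consecutive sleep episodes per participant starting
#' on a Monday. Morning types receive an earlier mean sleep midpoint and a
#' smaller night-to-night midpoint SD than evening types, so Composite Phase
#' Deviation correlates negatively with morningness. Friday and Saturday
#' nights are flagged as free nights and receive an oversleep extension.
#'
#' @param cohort Cohort with a `morning_person` column.
#' @param config A [sim_config()] (`n_nights`, `act_jitter_*`).
#' @param start_date First night for every participant, or `NULL` (default)
#'   to stagger wear periods over the Mondays of a calendar year so that
#'   season of actigraphy wear varies across participants.
#' @param oversleep_h Hours added to sleep duration on free nights.
#' @param seed Optional seed override.
#' @return A `data.frame` with columns `participant_id`, `night`, `date`,
#'   `sleep_onset`, `sleep_offset` (POSIXct, UTC) and `is_free_night`.
#' @export
simulate_actigraphy <- function(cohort, config,
                                start_date = NULL,
                                oversleep_h = 0.4, seed = NULL) {
  stopifnot(inherits(config, "sim_config"),
            "morning_person" %in% names(cohort))
  if (config$n_nights < 2)
    stop_config("n_nights", "must be >= 2 (CPD is undefined otherwise)")
  set.seed(seed %||% sub_seed(config$seed, 53L))

  n <- nrow(cohort)
  k <- config$n_nights
  starts <- if (is.null(start_date)) {
    as.Date("2015-01-05") + 7L * sample(0:51, n, replace = TRUE)
  } else {
    rep(as.Date(start_date), n)
  }
  # continuous hour axis anchored at midnight of the night's date: 27.4
  # corresponds to a 03:24 midpoint the following morning
  mu <- 27.4 - 0.7 * cohort$morning_person + stats::rnorm(n, 0, 0.5)
  jitter_sd <- ifelse(cohort$morning_person == 1,
                      config$act_jitter_morning, config$act_jitter_evening)

  dates <- rep(starts, times = k) + rep(seq_len(k) - 1L, each = n)
  weekday <- as.integer(format(dates, "%u"))   # 1 = Monday
  free <- weekday %in% c(5L, 6L)               # Friday / Saturday nights

  midpoint <- rep(mu, times = k) + stats::rnorm(n * k, 0, rep(jitter_sd, times = k))
  duration <- pmin(pmax(stats::rnorm(n * k, 8, 0.6), 2.5), 15.5)
  duration <- pmin(duration + ifelse(free, oversleep_h, 0), 15.5)

  onset_h <- midpoint - duration / 2
  midnight <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
  onset <- midnight + onset_h * 3600
  offset <- onset + duration * 3600

  data.frame(
    participant_id = rep(cohort$participant_id, times = k),
    night = rep(seq_len(k), each = n),
    date = dates,
    sleep_onset = onset,
    sleep_offset = offset,
    is_free_night = free,
    stringsAsFactors = FALSE
  )[order(rep(cohort$participant_id, times = k), rep(seq_len(k), each = n)), ]
}
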