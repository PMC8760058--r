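BINARY_OUTCOMES <- c("depressive_symptoms", "major_depression", "gad")
ORDINAL_OUTCOMES <- c("cidi_severity", "phq9_severity", "gad_severity",
                      "wellbeing_score")

#' Default outcome list
#' @return Character vector of the seven mental-health and wellbeing
#'   outcomes analysed by default.
#' @export
default_outcomes <- function() c(BINARY_OUTCOMES, ORDINAL_OUTCOMES)

season_of <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  cut(m, breaks = c(0, 2, 5, 8, 11, 12),
      labels = c("winter", "spring", "summer", "autumn", "winter2")) |>
    as.character() |>
    (\(x) factor(ifelse(x == "winter2", "winter", x),
                 levels = c("winter", "spring", "summer", "autumn")))()
}

# drop covariates that are constant within the analysed subset
usable_covariates <- function(data, covariates) {
  keep <- vapply(covariates, function(v) {
    x <- data[[v]]
    length(unique(x[!is.na(x)])) > 1
  }, logical(1))
  covariates[keep]
}

fit_outcome <- function(data, outcome, predictors, covariates) {
  covariates <- usable_covariates(data, covariates)
  if (outcome %in% BINARY_OUTCOMES ||
      length(unique(stats::na.omit(data[[outcome]]))) == 2) {
    fit_logistic(data, outcome, predictors, covariates)
  } else {
    fit_ordinal(data, outcome, predictors, covariates)
  }
}

result_row <- function(outcome, stratum, model, fit, term) {
  co <- fit$coefficients
  i <- match(term, co$term)
  data.frame(outcome = outcome, stratum = stratum, model = model,
             term = term, beta = co$beta[i], se = co$se[i], or = co$or[i],
             ci_low = co$ci_low[i], ci_high = co$ci_high[i], p = co$p[i],
             n = fit$n, stringsAsFactors = FALSE)
}

#' Remove participants reporting disturbed sleep
#'
#' Sensitivity exclusion: depression and anxiety questionnaires include
#' sleep-disturbance items that overlap the predictor, so flagged
#' individuals are removed before refitting.
#'
#' @param cohort Cohort with a `sleep_disturbed` flag column.
#' @return A list with `cohort` (the subset) and `n_excluded`.
#' @export
exclude_sleep_disturbed <- function(cohort) {
  if (!"sleep_disturbed" %in% names(cohort))
    stop_config("sleep_disturbed", "flag column absent from cohort")
  keep <- cohort$sleep_disturbed == 0
  list(cohort = cohort[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Observational models of mental health on standardised CPD
#'
#' Logistic / proportional-odds fits of each outcome on z-scored Composite
#' Phase Deviation, adjusted for age, sex and season of actigraphy wear,
#' optionally with additional adjustment for diurnal preference and the
#' morningness genetic risk score (to test that misalignment effects are
#' chronotype-independent).
#'
#' @param cpd_values `data.frame` from [cpd_table()] (column `cpd_primary`
#'   or `cpd_msfsc` selected by `measure`).
#' @param cohort Cohort with outcomes, `sex`, `age` and, for the adjusted
#'   variant, `morning_person`.
#' @param season Optional per-participant factor of actigraphy season,
#'   aligned to `cpd_values$participant_id`.
#' @param outcomes Outcomes to model.
#' @param measure `"cpd_primary"` or `"cpd_msfsc"`.
#' @param adjust_chronotype Add `morning_person` and, when supplied, the GRS
#'   to the adjustment set.
#' @param grs Optional `data.frame` with `participant_id` and `grs_s`.
#' @return `data.frame` of result rows (per-SD odds ratios for CPD).
#' @export
cpd_outcome_models <- function(cpd_values, cohort, season = NULL,
                               outcomes = default_outcomes(),
                               measure = "cpd_primary",
                               adjust_chronotype = FALSE, grs = NULL) {
  d <- merge(cpd_values, cohort, by = "participant_id")
  if (!is.null(season)) {
    s <- data.frame(participant_id = cpd_values$participant_id,
                    season = season, stringsAsFactors = FALSE)
    d <- merge(d, s, by = "participant_id")
  }
  d$cpd_z <- standardise_cpd(d[[measure]])
  covs <- c("age", "sex", if (!is.null(season)) "season")
  model_tag <- measure
  if (adjust_chronotype) {
    covs <- c(covs, "morning_person")
    model_tag <- paste0(model_tag, "_chronotype_adjusted")
    if (!is.null(grs)) {
      d <- merge(d, grs[, c("participant_id", "grs_s")], by = "participant_id")
      covs <- c(covs, "grs_s")
    }
  }
  rows <- lapply(outcomes, function(oc) {
    fit <- fit_outcome(d, oc, "cpd_z", covs)
    result_row(oc, "all", model_tag, fit, "cpd_z")
  })
  do.call(rbind, rows)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic-scale study
#'
#' Orchestrates, on one simulated cohort: observational regressions of each
#' outcome on diurnal preference at both adjustment tiers and in all /
#' male / female strata; one-sample MR (2SLS on the standardised GRS) per
#' outcome; two-sample MR (IVW, MR-Egger, weighted and penalised weighted
#' median) per binary outcome from disjoint simulated samples; CPD
#' observational models with and without chronotype/GRS adjustment plus the
#' diurnal-preference-to-CPD analyses; and Fisher's z sex-difference tests
#' for every paired male/female estimate. Results are returned as tables
#' and optionally written as TSVs with a JSON run manifest (seed + config
#' hash), so identical configurations reproduce byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory for TSVs and the manifest.
#' @param strata Strata for the diurnal-preference models.
#' @param n_boot Bootstrap replicates for median-estimator SEs.
#' @param sensitivity Also run the sleep-disturbance exclusion and
#'   shift-work stratification.
#' @return A list of class `chronomr_run`: `observational`,
#'   `mr_one_sample`, `mr_two_sample`, `cpd`, `sex_diff`, `instrument`,
#'   `manifest`.
#' @export
run_full <- function(config, out_dir = NULL,
                     strata = c("all", "male", "female"),
                     n_boot = 200, sensitivity = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_cohort(config)
  cohort <- sim$cohort
  genotypes <- sim$genotypes

  weights <- genotypes$variants_extra[
    , c("variant_id", "effect_allele", "other_allele", "beta")]
  grs_tab <- grs(genotypes, weights, qc_prob = NULL)
  cohort$grs_s <- grs_tab$grs_s[match(cohort$participant_id,
                                      grs_tab$participant_id)]
  strength <- instrument_strength(cohort$grs_s, cohort$morning_person)

  stratum_data <- function(stratum, d = cohort) {
    switch(stratum,
           all = d,
           male = d[d$sex == 1, , drop = FALSE],
           female = d[d$sex == 0, , drop = FALSE],
           shift = d[d$shift_worker == 1, , drop = FALSE],
           non_shift = d[d$shift_worker == 0, , drop = FALSE],
           stop("unknown stratum: ", stratum))
  }
  tiers <- list(minimal = c("age", "sex", "centre"),
                full = c("age", "sex", "centre", "tdi", "smoking", "bmi"))

  obs_rows <- list()
  for (oc in default_outcomes()) {
    for (tier in names(tiers)) {
      for (st in strata) {
        d <- stratum_data(st)
        fit <- fit_outcome(d, oc, "morning_person", tiers[[tier]])
        obs_rows[[length(obs_rows) + 1L]] <-
          result_row(oc, st, paste0("observational_", tier), fit,
                     "morning_person")
      }
    }
  }
  if (sensitivity) {
    excl <- exclude_sleep_disturbed(cohort)
    for (oc in default_outcomes()) {
      fit <- fit_outcome(excl$cohort, oc, "morning_person", tiers$full)
      obs_rows[[length(obs_rows) + 1L]] <-
        result_row(oc, "sleep_undisturbed", "observational_full", fit,
                   "morning_person")
    }
    for (st in c("shift", "non_shift")) {
      for (oc in c("depressive_symptoms", "wellbeing_score")) {
        fit <- fit_outcome(stratum_data(st), oc, "morning_person", tiers$full)
        obs_rows[[length(obs_rows) + 1L]] <-
          result_row(oc, st, "observational_full", fit, "morning_person")
      }
    }
  }
  observational <- do.call(rbind, obs_rows)

  one_rows <- list()
  for (oc in default_outcomes()) {
    for (st in strata) {
      d <- stratum_data(st)
      covs <- d[, usable_covariates(d, c("age", "sex", "centre")), drop = FALSE]
      est <- one_sample_tsls(d$grs_s, d$morning_person, d[[oc]],
                             covariates = covs)
      one_rows[[length(one_rows) + 1L]] <- data.frame(
        outcome = oc, stratum = st, model = "mr_one_sample_tsls",
        term = "fitted_exposure", beta = est$beta, se = est$se,
        or = exp(est$beta), ci_low = exp(est$ci_low),
        ci_high = exp(est$ci_high), p = est$p, n = est$n,
        stringsAsFactors = FALSE)
    }
  }
  mr_one_sample <- do.call(rbind, one_rows)

  # two-sample: one exposure sample, one disjoint outcome sample, per-SNP
  # scans per binary outcome
  g1 <- simulate_genotypes(config)
  c1 <- simulate_exposure(g1, config)
  exp_scan <- snp_linear_scan(g1$dosages, c1$liability)
  g2 <- simulate_genotypes(config, variants = g1$variants_extra,
                           seed = sub_seed(config$seed, 101L))
  c2 <- simulate_exposure(g2, config, seed = sub_seed(config$seed, 103L))
  c2 <- simulate_outcomes(c2, g2, config, seed = sub_seed(config$seed, 107L))
  two_rows <- list()
  for (oc in BINARY_OUTCOMES) {
    out_scan <- snp_logistic_scan(g2$dosages, c2[[oc]])
    h <- data.frame(variant_id = g1$variants_extra$variant_id,
                    beta_exposure = exp_scan$beta, se_exposure = exp_scan$se,
                    beta_outcome = out_scan$beta, se_outcome = out_scan$se)
    class(h) <- c("harmonised_summary", "data.frame")
    fits <- mr_twosample(h, n_boot = n_boot,
                         seed = sub_seed(config$seed, 131L))
    for (f in fits) {
      two_rows[[length(two_rows) + 1L]] <- data.frame(
        outcome = oc, stratum = "all", model = paste0("mr_", f$method),
        term = "causal_slope", beta = f$beta, se = f$se, or = exp(f$beta),
        ci_low = exp(f$ci_low), ci_high = exp(f$ci_high), p = f$p,
        n = f$n_snps, stringsAsFactors = FALSE)
    }
  }
  mr_two_sample <- do.call(rbind, two_rows)

  # CPD analyses
  act <- simulate_actigraphy(cohort, config)
  cpd_tab <- cpd_table(act)
  first_dates <- vapply(split(as.character(act$date), act$participant_id),
                        min, character(1))
  season <- season_of(first_dates[cpd_tab$participant_id])
  cpd_rows <- list(
    cpd_outcome_models(cpd_tab, cohort, season = season),
    cpd_outcome_models(cpd_tab, cohort, season = season,
                       adjust_chronotype = TRUE, grs = grs_tab),
    cpd_outcome_models(cpd_tab, cohort, season = season,
                       measure = "cpd_msfsc"))
  cpd_merged <- merge(cpd_tab, cohort, by = "participant_id")
  cpd_merged$cpd_z <- standardise_cpd(cpd_merged$cpd_primary)
  obs_cpd <- stats::lm(cpd_z ~ morning_person + age + sex, data = cpd_merged)
  sm <- summary(obs_cpd)$coefficients
  cpd_rows[[length(cpd_rows) + 1L]] <- data.frame(
    outcome = "cpd", stratum = "all", model = "observational_linear",
    term = "morning_person", beta = sm["morning_person", 1],
    se = sm["morning_person", 2], or = NA_real_,
    ci_low = sm["morning_person", 1] - 1.96 * sm["morning_person", 2],
    ci_high = sm["morning_person", 1] + 1.96 * sm["morning_person", 2],
    p = sm["morning_person", 4], n = nrow(cpd_merged),
    stringsAsFactors = FALSE)
  tsls_cpd <- one_sample_tsls(cpd_merged$grs_s, cpd_merged$morning_person,
                              cpd_merged$cpd_z,
                              covariates = cpd_merged[, c("age", "sex")])
  cpd_rows[[length(cpd_rows) + 1L]] <- data.frame(
    outcome = "cpd", stratum = "all", model = "mr_one_sample_tsls",
    term = "fitted_exposure", beta = tsls_cpd$beta, se = tsls_cpd$se,
    or = NA_real_, ci_low = tsls_cpd$ci_low, ci_high = tsls_cpd$ci_high,
    p = tsls_cpd$p, n = tsls_cpd$n, stringsAsFactors = FALSE)
  cpd_results <- do.call(rbind, cpd_rows)

  # Fisher z sex differences for every paired male/female estimate
  paired <- rbind(observational, mr_one_sample)
  sex_rows <- list()
  for (key in unique(paste(paired$outcome, paired$model))) {
    sub <- paired[paste(paired$outcome, paired$model) == key, ]
    m <- sub[sub$stratum == "male", ]
    f <- sub[sub$stratum == "female", ]
    if (nrow(m) == 1 && nrow(f) == 1) {
      fz <- fishers_z(m$beta, m$se, f$beta, f$se)
      sex_rows[[length(sex_rows) + 1L]] <- data.frame(
        outcome = m$outcome, model = m$model, beta_m = fz$beta_m,
        se_m = fz$se_m, beta_f = fz$beta_f, se_f = fz$se_f, z = fz$z,
        p = fz$p, stringsAsFactors = FALSE)
    }
  }
  sex_diff <- do.call(rbind, sex_rows)

  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   n_individuals = config$n_individuals,
                   n_snps = config$n_snps,
                   instrument_r2 = strength$r_squared,
                   instrument_f = strength$f_statistic)

  res <- list(observational = observational, mr_one_sample = mr_one_sample,
              mr_two_sample = mr_two_sample, cpd = cpd_results,
              sex_diff = sex_diff, instrument = strength,
              manifest = manifest)
  class(res) <- "chronomr_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("observational", "mr_one_sample", "mr_two_sample", "cpd",
                 "sex_diff")) {
      write_tsv(res[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.chronomr_run <- function(x, ...) {
  cat("chronomr run:",
      nrow(x$observational), "observational rows,",
      nrow(x$mr_one_sample), "one-sample MR rows,",
      nrow(x$mr_two_sample), "two-sample MR rows,",
      nrow(x$cpd), "CPD rows\n")
  cat(sprintf("instrument r2 = %.3f, first-stage F = %.1f, config %s\n",
              x$instrument$r_squared, x$instrument$f_statistic,
              x$manifest$config_hash))
  invisible(x)
}
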