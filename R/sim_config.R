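#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles and validates every parameter of the synthetic-cohort machinery.
#' The defaults describe the study conditions the package emulates: a large
#' population cohort in which roughly 62.6% classify themselves as morning
#' people, a genetic risk score explaining 5.4% of the variance in the
#' liability to morningness, and a modest protective causal effect of
#' morningness on depression-like binary outcomes.
#'
#' @param n_individuals Number of participants per simulated cohort.
#' @param n_snps Number of independent biallelic instrument SNPs.
#' @param maf_range Length-2 numeric in (0, 1): minor-allele-frequency range
#'   from which per-SNP frequencies are drawn uniformly.
#' @param grs_liability_r2 Fraction of exposure-liability variance explained
#'   by the true genetic risk score, in \[0, 1).
#' @param confounder_effect_exposure Effect (per SD of the confounder) on the
#'   exposure liability.
#' @param confounder_effect_outcome Effect (log-odds per SD of the
#'   confounder) on each outcome.
#' @param causal_lnor True causal log odds ratio of being a morning person on
#'   each binary mental-health outcome (negative = protective). The wellbeing
#'   score receives the negated effect, since higher wellbeing is the
#'   beneficial direction.
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`: how direct SNP-to-outcome effects are drawn for
#'   the invalid instruments.
#' @param invalid_fraction Fraction of SNPs given a pleiotropic effect.
#' @param pleiotropy_sd Scale (log-odds) of the pleiotropic effects.
#' @param outcome_prevalence Target marginal prevalence of the primary binary
#'   outcome (depressive symptoms), in (0, 1).
#' @param case_fraction Fraction of the cohort classified as morning people
#'   (the liability threshold is the matching quantile).
#' @param n_nights Number of actigraphy nights per participant (>= 2).
#' @param act_jitter_morning,act_jitter_evening Night-to-night SD (hours) of
#'   the sleep midpoint for morning and evening types. The evening value is
#'   larger so that Composite Phase Deviation correlates negatively with
#'   morningness, as observed in actigraphy cohorts.
#' @param flip_fraction Fraction of SNPs whose outcome summary statistics are
#'   reported on the swapped allele, to exercise harmonisation.
#' @param missing_rate Optional MCAR missingness rate applied to covariates.
#' @param seed Integer seed; fully determines all generator output.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 500, n_snps = 20, seed = 7)
#' cfg$grs_liability_r2
sim_config <- function(n_individuals = 10000,
                       n_snps = 100,
                       maf_range = c(0.05, 0.5),
                       grs_liability_r2 = 0.054,
                       confounder_effect_exposure = 0.3,
                       confounder_effect_outcome = 0.3,
                       causal_lnor = -0.12,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "inside_violating"),
                       invalid_fraction = 0,
                       pleiotropy_sd = 0.05,
                       outcome_prevalence = 0.11,
                       case_fraction = 0.626,
                       n_nights = 7,
                       act_jitter_morning = 0.7,
                       act_jitter_evening = 0.8,
                       flip_fraction = 0,
                       missing_rate = 0,
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)

  if (!is.numeric(n_individuals) || length(n_individuals) != 1 || n_individuals < 1)
    stop_config("n_individuals", "must be a positive count")
  if (!is.numeric(n_snps) || length(n_snps) != 1 || n_snps < 1)
    stop_config("n_snps", "must be >= 1")
  if (length(maf_range) != 2 || any(maf_range < 0) || any(maf_range >= 1) ||
      maf_range[1] > maf_range[2])
    stop_config("maf_range", "must be an ordered pair within [0, 1)")
  if (grs_liability_r2 < 0 || grs_liability_r2 >= 1)
    stop_config("grs_liability_r2", "must lie in [0, 1)")
  if (invalid_fraction < 0 || invalid_fraction > 1)
    stop_config("invalid_fraction", "must lie in [0, 1]")
  if (outcome_prevalence <= 0 || outcome_prevalence >= 1)
    stop_config("outcome_prevalence", "must lie strictly in (0, 1)")
  if (case_fraction <= 0 || case_fraction >= 1)
    stop_config("case_fraction", "must lie strictly in (0, 1)")
  if (n_nights < 2)
    stop_config("n_nights", "must be >= 2 (CPD is undefined otherwise)")
  if (flip_fraction < 0 || flip_fraction > 1)
    stop_config("flip_fraction", "must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_config("missing_rate", "must lie in [0, 1)")
  if (!is.numeric(seed) || length(seed) != 1)
    stop_config("seed", "must be a single integer")

  structure(list(
    n_individuals = as.integer(n_individuals),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    grs_liability_r2 = grs_liability_r2,
    confounder_effect_exposure = confounder_effect_exposure,
    confounder_effect_outcome = confounder_effect_outcome,
    causal_lnor = causal_lnor,
    pleiotropy_mode = pleiotropy_mode,
    invalid_fraction = invalid_fraction,
    pleiotropy_sd = pleiotropy_sd,
    outcome_prevalence = outcome_prevalence,
    case_fraction = case_fraction,
    n_nights = as.integer(n_nights),
    act_jitter_morning = act_jitter_morning,
    act_jitter_evening = act_jitter_evening,
    flip_fraction = flip_fraction,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}
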