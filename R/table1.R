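#' Published cohort descriptives for morning and evening people
#'
#' Aggregate case counts and group sizes for morning- versus evening-person
#' groups from the descriptive table of a large UK population cohort, shipped
#' as a plain-text worked example. These counts drive two exactly
#' recomputable checks: group percentages (`100 * cases / n_group`, which
#' reproduce the published one-decimal percentages) and the closed-form
#' unadjusted odds ratio `ad / bc` with log-scale standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)` that any logistic fit on the saturated 2x2
#' design must match.
#'
#' @return `data.frame` with columns `measure`, `group`, `cases`, `n_group`,
#'   `printed_pct` and a computed `pct` column.
#' @export
#' @examples
#' head(cohort_descriptives())
cohort_descriptives <- function() {
  path <- system.file("extdata", "cohort_descriptives.tsv",
                      package = "chronomr", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$pct <- 100 * d$cases / d$n_group
  d
}

#' Closed-form 2x2 odds ratio with log-scale standard error
#'
#' For exposure-outcome counts `a` (exposed cases), `b` (exposed
#' non-cases), `c` (unexposed cases), `d` (unexposed non-cases):
#' `OR = ad / bc`, `se(ln OR) = sqrt(1/a + 1/b + 1/c + 1/d)`. This is the
#' saturated-model maximum-likelihood estimate, so a logistic regression on
#' the same 2x2 data reproduces it exactly.
#'
#' @param a,b,c,d Cell counts.
#' @return List with `or`, `lnor`, `se`, `ci_low`, `ci_high` (OR scale).
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  lnor <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ci <- wald_ci(lnor, se)
  list(or = exp(lnor), lnor = lnor, se = se,
       ci_low = exp(ci[, "low"]), ci_high = exp(ci[, "high"]))
}
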