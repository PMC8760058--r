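#' Genotype dosage matrix
#'
#' Container pairing a participants-by-variants dosage matrix with the
#' variant annotation describing which allele each dosage counts.
#'
#' @param dosages Numeric matrix, participants in rows (rownames = ids),
#'   variants in columns (colnames = variant ids), dosages in \[0, 2\]
#'   (NA allowed after QC).
#' @param variants `data.frame` with columns `variant_id`, `counted_allele`
#'   (the allele the dosage counts; `effect_allele` is accepted as an alias)
#'   and `other_allele`, one row per dosage column, same order.
#' @param probs Optional matrix of per-genotype call probabilities, same
#'   shape as `dosages`.
#' @param variants_extra Internal: full simulation variant table.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, probs = NULL,
                            variants_extra = NULL) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  nm <- names(variants)
  nm[nm == "effect_allele"] <- "counted_allele"
  names(variants) <- nm
  stopifnot(all(c("variant_id", "counted_allele", "other_allele") %in% names(variants)),
            nrow(variants) == ncol(dosages))
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (!is.null(probs)) stopifnot(all(dim(probs) == dim(dosages)))
  colnames(dosages) <- variants$variant_id
  structure(list(dosages = dosages, variants = variants, probs = probs,
                 variants_extra = variants_extra),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d participants x %d variants%s\n",
              nrow(x$dosages), ncol(x$dosages),
              if (is.null(x$probs)) "" else " (with call probabilities)"))
  invisible(x)
}

#' Harmonise a genotype matrix to the morningness alleles
#'
#' Recodes dosages so that every counted allele is the morningness
#' (exposure-increasing) allele of the weight table: where the matrix counts
#' the other allele the dosage is complemented (`d -> 2 - d`), strand flips
#' are resolved by allele complement, and variants with a negative weight
#' are flipped so all weights end up positive. GRS ranks are invariant under
#' these recodings.
#'
#' @param weights `data.frame` with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`.
#' @param genotypes A [genotype_matrix()].
#' @return A list with `genotypes` (recoded matrix, counted allele = the
#'   positively weighted morningness allele), `weights` (all `beta > 0`),
#'   `missing` (weight variants absent from the matrix) and `unresolved`
#'   (variants whose alleles matched in neither orientation; these raise an
#'   error unless empty).
#' @export
harmonise_alleles <- function(weights, genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            all(c("variant_id", "effect_allele", "other_allele", "beta") %in%
                  names(weights)))
  if (!all(is.finite(weights$beta))) stop("weights must be finite")
  if (any(weights$effect_allele == weights$other_allele))
    stop("effect and other allele identical for some variants")

  v <- genotypes$variants
  idx <- match(weights$variant_id, v$variant_id)
  missing <- weights$variant_id[is.na(idx)]
  keep <- !is.na(idx)
  w <- weights[keep, , drop = FALSE]
  gi <- idx[keep]

  dos <- genotypes$dosages
  probs <- genotypes$probs
  unresolved <- character(0)

  for (k in seq_along(gi)) {
    j <- gi[k]
    ca <- v$counted_allele[j]; oa <- v$other_allele[j]
    ea <- w$effect_allele[k]; wo <- w$other_allele[k]
    if (ca == ea && oa == wo) {
      # already counted on the effect allele
    } else if (ca == wo && oa == ea) {
      dos[, j] <- 2 - dos[, j]
      v$counted_allele[j] <- ea; v$other_allele[j] <- wo
    } else if (complement_allele(ca) == ea && complement_allele(oa) == wo) {
      v$counted_allele[j] <- ea; v$other_allele[j] <- wo
    } else if (complement_allele(ca) == wo && complement_allele(oa) == ea) {
      dos[, j] <- 2 - dos[, j]
      v$counted_allele[j] <- ea; v$other_allele[j] <- wo
    } else {
      unresolved <- c(unresolved, w$variant_id[k])
    }
  }
  if (length(unresolved))
    stop("allele mismatch with neither orientation valid for: ",
         paste(unresolved, collapse = ", "))

  # orient negative weights to the opposite allele so all weights are positive
  neg <- which(w$beta < 0)
  for (k in neg) {
    j <- gi[k]
    dos[, j] <- 2 - dos[, j]
    tmp <- v$counted_allele[j]
    v$counted_allele[j] <- v$other_allele[j]; v$other_allele[j] <- tmp
    w$other_allele[k] <- w$effect_allele[k]; w$effect_allele[k] <- v$counted_allele[j]
    w$beta[k] <- -w$beta[k]
  }

  g_out <- genotype_matrix(dos[, gi, drop = FALSE],
                           v[gi, , drop = FALSE],
                           probs = if (is.null(probs)) NULL else probs[, gi, drop = FALSE])
  list(genotypes = g_out, weights = w, missing = missing,
       unresolved = unresolved)
}

#' Mask low-confidence genotype calls
#'
#' Sets dosages whose call probability is strictly below `prob_threshold` to
#' missing. Scores are later computed over the remaining variants with
#' renormalised weights (see [grs_weighted()]).
#'
#' @param genotypes A [genotype_matrix()]; if it carries no probability
#'   channel the matrix is returned unchanged with a message.
#' @param prob_threshold Probability threshold in \[0, 1\] (default 0.9).
#' @return The filtered [genotype_matrix()].
#' @export
qc_filter <- function(genotypes, prob_threshold = 0.9) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (prob_threshold < 0 || prob_threshold > 1)
    stop("prob_threshold must lie in [0, 1]")
  if (is.null(genotypes$probs)) {
    message("no genotype probability channel: qc_filter is a pass-through")
    return(genotypes)
  }
  genotypes$dosages[genotypes$probs < prob_threshold] <- NA_real_
  genotypes
}

#' Weighted genetic risk score
#'
#' `GRS_w = sum_i beta_i * d_i` over the harmonised instrument variants.
#' With missing dosages (after QC) the sum runs over non-missing variants
#' and, by default, is rescaled by `sum(all beta) / sum(used beta)` so
#' scores remain comparable across participants; mean imputation of the
#' missing dosages is available as an alternative.
#'
#' @param genotypes Harmonised [genotype_matrix()].
#' @param weights Harmonised weight table (`beta` aligned to the counted
#'   alleles).
#' @param missing One of `"renormalise"` (default), `"mean_impute"`, `"none"`
#'   (missing dosages contribute zero, unscaled).
#' @return Named numeric vector of per-participant scores with attribute
#'   `n_used` (non-missing variants per participant).
#' @export
grs_weighted <- function(genotypes, weights,
                         missing = c("renormalise", "mean_impute", "none")) {
  missing <- match.arg(missing)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  idx <- match(genotypes$variants$variant_id, weights$variant_id)
  if (all(is.na(idx))) stop("no overlapping variants between weights and genotypes")
  if (anyNA(idx)) stop("genotype matrix contains variants absent from the weight table")
  beta <- weights$beta[idx]

  d <- genotypes$dosages
  obs <- !is.na(d)
  n_used <- rowSums(obs)
  if (missing == "mean_impute" && any(!obs)) {
    mu <- colMeans(d, na.rm = TRUE)
    for (j in which(colSums(!obs) > 0)) d[!obs[, j], j] <- mu[j]
    obs[] <- TRUE
  }
  d0 <- d; d0[!obs] <- 0
  raw <- drop(d0 %*% beta)
  if (missing == "renormalise") {
    beta_used <- drop(obs %*% beta)
    scale <- ifelse(beta_used > 0, sum(beta) / beta_used, NA_real_)
    raw <- raw * scale
  }
  names(raw) <- rownames(genotypes$dosages)
  attr(raw, "n_used") <- n_used
  raw
}

#' Standardised genetic risk score
#'
#' `GRS_s = n * GRS_w / sum(beta)`: rescales the weighted score to the
#' morningness-allele-count metric, so values lie in \[0, 2n\] and a unit
#' step is one average-effect allele.
#'
#' @param grs_w Weighted scores from [grs_weighted()].
#' @param weights Harmonised weight table (all `beta > 0`).
#' @param n_variants Number of instrument variants `n`; defaults to
#'   `nrow(weights)`.
#' @return Numeric vector of standardised scores.
#' @export
grs_standardised <- function(grs_w, weights, n_variants = nrow(weights)) {
  s <- sum(weights$beta)
  if (s <= 0)
    stop("sum of weights is not positive; harmonise_alleles() was skipped")
  n_variants * grs_w / s
}

#' Compute both genetic risk scores from raw inputs
#'
#' Convenience wrapper: harmonises alleles, applies the genotype-probability
#' QC and returns both score forms.
#'
#' @param genotypes A [genotype_matrix()].
#' @param weights Variant-weight table.
#' @param qc_prob Probability threshold passed to [qc_filter()]
#'   (`NULL` to skip).
#' @param missing Missing-dosage policy for [grs_weighted()].
#' @return `data.frame` with `participant_id`, `grs_w`, `grs_s`, `n_used`.
#' @export
grs <- function(genotypes, weights, qc_prob = 0.9,
                missing = "renormalise") {
  h <- harmonise_alleles(weights, genotypes)
  g <- h$genotypes
  if (!is.null(qc_prob) && !is.null(g$probs)) g <- qc_filter(g, qc_prob)
  w <- grs_weighted(g, h$weights, missing = missing)
  s <- grs_standardised(w, h$weights)
  data.frame(participant_id = names(w), grs_w = as.numeric(w),
             grs_s = as.numeric(s), n_used = attr(w, "n_used"),
             stringsAsFactors = FALSE)
}

#' Instrument strength of a genetic risk score
#'
#' Reports the squared Pearson correlation between the score and the binary
#' exposure (the variance-explained convention used here), McFadden's
#' pseudo-R2 from a univariable logistic fit, and the first-stage regression
#' F statistic used for weak-instrument screening.
#'
#' @param grs Numeric score vector.
#' @param exposure Binary (0/1) exposure of the same length.
#' @return A list with `r_squared`, `mcfadden_r2`, `f_statistic` and `n`.
#' @export
instrument_strength <- function(grs, exposure) {
  stopifnot(length(grs) == length(exposure))
  ok <- stats::complete.cases(grs, exposure)
  grs <- grs[ok]; exposure <- exposure[ok]
  if (length(unique(exposure)) < 2) stop("exposure is constant")
  r2 <- stats::cor(grs, exposure)^2
  fit <- stats::lm(exposure ~ grs)
  fstat <- summary(fit)$fstatistic[["value"]]
  lfit <- stats::glm(exposure ~ grs, family = stats::binomial())
  lnull <- stats::glm(exposure ~ 1, family = stats::binomial())
  mcfadden <- 1 - as.numeric(stats::logLik(lfit) / stats::logLik(lnull))
  list(r_squared = r2, mcfadden_r2 = mcfadden, f_statistic = fstat,
       n = length(grs))
}
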