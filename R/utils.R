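#' @keywords internal
"_PACKAGE"

# DNA complement lookup used by allele harmonisation
.complement <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) {
  out <- unname(.complement[x])
  if (anyNA(out)) stop("non-ACGT allele: ", paste(x[is.na(out)], collapse = ", "))
  out
}

is_palindromic <- function(a1, a2) complement_allele(a1) == a2

# Deterministic sub-seed: each generator draws from its own stream so that
# adding or reordering downstream draws never perturbs upstream ones.
sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2011L + as.integer(offset)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

wald_ci <- function(beta, se, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  cbind(low = beta - z * se, high = beta + z * se)
}

wald_p <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))
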