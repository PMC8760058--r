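#' Read a variant-weight table
#'
#' TSV with header `variant_id, effect_allele, other_allele, beta`.
#'
#' @param path File path.
#' @return `data.frame` of variant weights.
#' @export
read_variant_weights <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele", "beta")
  if (!all(need %in% names(w)))
    stop("weight file must have columns: ", paste(need, collapse = ", "))
  w
}

#' Read a genotype dosage table
#'
#' TSV with a `participant_id` column followed by one column per variant.
#' Allele annotation comes from the accompanying weight table: the counted
#' allele is assumed to be the weight table's effect allele unless a
#' separate variant annotation is supplied.
#'
#' @param path File path.
#' @param variants Variant annotation `data.frame` (`variant_id`,
#'   `counted_allele`/`effect_allele`, `other_allele`).
#' @return A [genotype_matrix()].
#' @export
read_dosages <- function(path, variants) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("participant_id" %in% names(d))
  ids <- d$participant_id
  m <- as.matrix(d[, setdiff(names(d), "participant_id"), drop = FALSE])
  rownames(m) <- ids
  v <- variants[match(colnames(m), variants$variant_id), , drop = FALSE]
  if (anyNA(v$variant_id)) stop("dosage columns missing from variant annotation")
  genotype_matrix(m, v)
}

#' Read a phenotype/covariate table (CSV)
#' @param path File path.
#' @return `data.frame`.
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read GWAS-style summary statistics
#'
#' TSV with header `variant_id, effect_allele, other_allele, eaf, beta, se,
#' p, n`.
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
read_summary_stats <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  if (!all(need %in% names(s)))
    stop("summary-stats file must have columns: ", paste(need, collapse = ", "))
  s
}

#' Read per-night actigraphy sleep records (CSV, ISO-8601 datetimes)
#' @param path File path.
#' @return `data.frame` with POSIXct onset/offset columns.
#' @export
read_actigraphy <- function(path) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "date", "sleep_onset", "sleep_offset")
  if (!all(need %in% names(a)))
    stop("actigraphy file must have columns: ", paste(need, collapse = ", "))
  a$date <- as.Date(a$date)
  a$sleep_onset <- as.POSIXct(a$sleep_onset, tz = "UTC",
                              format = "%Y-%m-%dT%H:%M:%S")
  a$sleep_offset <- as.POSIXct(a$sleep_offset, tz = "UTC",
                               format = "%Y-%m-%dT%H:%M:%S")
  a
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated study to disk in the standard input formats
#'
#' Emits the five file types the pipeline consumes (variant-weight TSV,
#' dosage TSV, phenotype CSV, exposure/outcome summary-stat TSVs, actigraphy
#' CSV) plus a `truth.json` sidecar recording the simulation parameters.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  act <- simulate_actigraphy(sim$cohort, config)
  ss <- make_two_sample_stats(config)

  v <- sim$genotypes$variants_extra
  paths <- c(
    weights = file.path(dir, "weights.tsv"),
    dosages = file.path(dir, "dosages.tsv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    exposure_stats = file.path(dir, "exposure_stats.tsv"),
    outcome_stats = file.path(dir, "outcome_stats.tsv"),
    actigraphy = file.path(dir, "actigraphy.csv"),
    truth = file.path(dir, "truth.json"))

  write_tsv(v[, c("variant_id", "effect_allele", "other_allele", "beta")],
            paths["weights"])
  write_tsv(cbind(participant_id = rownames(sim$genotypes$dosages),
                  as.data.frame(sim$genotypes$dosages)), paths["dosages"])
  pheno <- sim$cohort
  pheno$liability <- NULL
  pheno$confounder <- NULL
  utils::write.csv(pheno, paths["phenotypes"], row.names = FALSE, quote = FALSE)
  write_tsv(ss$exposure, paths["exposure_stats"])
  write_tsv(ss$outcome, paths["outcome_stats"])
  act_out <- act
  act_out$sleep_onset <- format(act$sleep_onset, "%Y-%m-%dT%H:%M:%S")
  act_out$sleep_offset <- format(act$sleep_offset, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(act_out, paths["actigraphy"], row.names = FALSE, quote = FALSE)

  truth <- attr(sim$cohort, "truth")
  jsonlite::write_json(
    list(config = unclass(config),
         grs_scale = truth$grs_scale,
         gamma = truth$gamma,
         alphas = as.list(truth$alphas)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
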