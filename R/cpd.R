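#' Sleep midpoint on a continuous hour axis
#'
#' The midpoint is `onset + duration / 2`, expressed in hours since midnight
#' of the night's date. Values may exceed 24 for post-midnight midpoints,
#' which keeps cross-midnight sleep free of modular discontinuity: a 23:30
#' onset with a 07:30 offset has midpoint 27.5 (03:30 the next morning).
#'
#' @param onset,offset POSIXct sleep onset and offset.
#' @param night_date The calendar date each night is anchored to (defaults
#'   to the onset date, which is only correct when onset precedes midnight).
#' @param min_duration,max_duration Plausibility bounds in hours; records
#'   outside `(min_duration, max_duration)` are rejected.
#' @return `data.frame` with `midsleep` and `duration` in hours, plus
#'   `ok` (logical) and `reason` (`NA`, `"nonpositive_duration"` or
#'   `"implausible_duration"`).
#' @export
#' @examples
#' on <- as.POSIXct("2015-03-02 23:30:00", tz = "UTC")
#' off <- as.POSIXct("2015-03-03 07:30:00", tz = "UTC")
#' midsleep(on, off)
midsleep <- function(onset, offset, night_date = as.Date(onset),
                     min_duration = 2, max_duration = 16) {
  duration <- as.numeric(difftime(offset, onset, units = "hours"))
  midnight <- as.POSIXct(paste(night_date, "00:00:00"),
                         tz = attr(onset, "tzone") %||% "UTC")
  onset_h <- as.numeric(difftime(onset, midnight, units = "hours"))
  mid <- onset_h + duration / 2
  reason <- rep(NA_character_, length(duration))
  reason[duration <= 0] <- "nonpositive_duration"
  reason[duration > 0 & (duration <= min_duration | duration >= max_duration)] <-
    "implausible_duration"
  ok <- is.na(reason)
  mid[!ok] <- NA_real_
  data.frame(midsleep = mid, duration = duration, ok = ok, reason = reason,
             stringsAsFactors = FALSE)
}

#' MSFsc reference midpoint (oversleep-corrected free-night mean)
#'
#' `MSFsc = MSF - (SD_free - SD_week) / 2` when mean free-night sleep
#' duration exceeds the all-night mean, else `MSF`, where `MSF` is the mean
#' midpoint over free (Friday/Saturday) nights. The one-sided correction
#' removes the midpoint shift produced by weekend oversleep.
#'
#' @param midsleeps Numeric midpoints (continuous hours).
#' @param free Logical free-night flags, same length.
#' @param durations Sleep durations in hours, same length.
#' @return The reference midpoint in hours.
#' @export
msfsc_reference <- function(midsleeps, free, durations) {
  stopifnot(length(midsleeps) == length(free),
            length(midsleeps) == length(durations))
  if (!any(free)) stop("no free nights: MSFsc reference undefined")
  msf <- mean(midsleeps[free])
  sd_free <- mean(durations[free])
  sd_week <- mean(durations)
  if (sd_free > sd_week) msf - (sd_free - sd_week) / 2 else msf
}

#' Composite Phase Deviation (CPD)
#'
#' For consecutive nights `i = 2..n` the per-night deviation is the
#' Euclidean combination of the mistiming and irregularity components,
#' `sqrt((MS_i - ref)^2 + (MS_i - MS_(i-1))^2)`, and CPD is their mean over
#' nights 2..n (the first night has no previous-night term and contributes
#' none). The reference is either the individual's all-night mean midpoint
#' (primary) or the oversleep-corrected free-night mean ([msfsc_reference()];
#' sensitivity variant). CPD is non-negative, zero only for a constant
#' series, and invariant to shifting all midpoints by a constant.
#'
#' @param midsleeps Ordered numeric midpoints (continuous hours), one per
#'   night.
#' @param reference `"all_night_mean"` or `"msfsc"`.
#' @param free Logical free-night flags (required for `"msfsc"`).
#' @param durations Sleep durations in hours (required for `"msfsc"`).
#' @return A list of class `cpd_result`: `cpd` (hours), `n_nights_used`,
#'   `reference` (hours) and `method`.
#' @export
#' @examples
#' cpd(c(3, 4, 2))$cpd   # 1.8251
cpd <- function(midsleeps, reference = c("all_night_mean", "msfsc"),
                free = NULL, durations = NULL) {
  reference <- match.arg(reference)
  ms <- midsleeps[is.finite(midsleeps)]
  if (length(ms) < 2)
    return(structure(list(cpd = NA_real_, n_nights_used = length(ms),
                          reference = NA_real_, method = reference,
                          flag = "fewer_than_2_usable_nights"),
                     class = "cpd_result"))
  ref <- if (reference == "all_night_mean") {
    mean(ms)
  } else {
    if (is.null(free) || is.null(durations))
      stop("msfsc reference requires free-night flags and durations")
    keep <- is.finite(midsleeps)
    msfsc_reference(midsleeps[keep], free[keep], durations[keep])
  }
  i <- 2:length(ms)
  per_night <- sqrt((ms[i] - ref)^2 + (ms[i] - ms[i - 1])^2)
  structure(list(cpd = mean(per_night), n_nights_used = length(ms),
                 reference = ref, method = reference, flag = NA_character_),
            class = "cpd_result")
}

#' @export
print.cpd_result <- function(x, ...) {
  cat(sprintf("CPD (%s): %.4f h over %d nights (reference %.2f h)\n",
              x$method, x$cpd, x$n_nights_used, x$reference))
  invisible(x)
}

#' Per-participant CPD from raw sleep records
#'
#' Computes midpoints with [midsleep()] and both CPD variants per
#' participant. Participants with fewer than `min_nights` usable nights get
#' `NA` with a flag; the MSFsc variant is `NA` where a participant has no
#' usable free night.
#'
#' @param records `data.frame` with columns `participant_id`, `date`,
#'   `sleep_onset`, `sleep_offset` and optionally `is_free_night` (inferred
#'   from `date` weekday when absent).
#' @param min_nights Minimum usable nights for inclusion (default 5).
#' @return `data.frame` with `participant_id`, `cpd_primary`, `cpd_msfsc`,
#'   `n_nights_used`.
#' @export
cpd_table <- function(records, min_nights = 5) {
  stopifnot(all(c("participant_id", "date", "sleep_onset", "sleep_offset") %in%
                  names(records)))
  if (!"is_free_night" %in% names(records)) {
    records$is_free_night <- as.integer(format(as.Date(records$date), "%u")) %in%
      c(5L, 6L)
  }
  ms <- midsleep(records$sleep_onset, records$sleep_offset,
                 night_date = as.Date(records$date))
  records$midsleep <- ms$midsleep
  records$duration <- ms$duration
  records <- records[order(records$participant_id, as.Date(records$date)), ]

  out <- lapply(split(records, records$participant_id), function(d) {
    ok <- is.finite(d$midsleep)
    n_ok <- sum(ok)
    primary <- msfsc <- NA_real_
    if (n_ok >= max(2, min_nights)) {
      primary <- cpd(d$midsleep[ok])$cpd
      if (any(d$is_free_night[ok]))
        msfsc <- cpd(d$midsleep[ok], reference = "msfsc",
                     free = d$is_free_night[ok], durations = d$duration[ok])$cpd
    }
    data.frame(participant_id = d$participant_id[1], cpd_primary = primary,
               cpd_msfsc = msfsc, n_nights_used = n_ok,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Standardise CPD values to z-scores
#'
#' Centres and scales over the analysis sample so downstream effects are
#' reported per SD of CPD. The population-SD convention (divide by n) is the
#' default and is recorded alongside the scores.
#'
#' @param values Numeric CPD values (NA dropped from the mean/SD).
#' @param sd_type `"population"` (divide by n) or `"sample"` (n - 1).
#' @return Numeric z-scores with attributes `mean` and `sd`.
#' @export
standardise_cpd <- function(values, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- values[is.finite(values)]
  if (length(x) < 2) stop("need at least 2 values to standardise")
  m <- mean(x)
  s <- stats::sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  if (!is.finite(s) || s == 0) stop("zero SD: cannot standardise")
  z <- (values - m) / s
  attr(z, "mean") <- m
  attr(z, "sd") <- s
  z
}
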