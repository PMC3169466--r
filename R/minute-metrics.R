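# Per-minute reduction of an attempt's event stream.
#
# Minute m (1-based) covers the half-open window [60*(m-1), 60*m) seconds.
# Depth: arithmetic mean of the peak depths of compressions whose time falls
# in the window.  Rate: *instantaneous* (active-compression) rate, 60 divided
# by the mean of the inter-compression intervals attributed to the window;
# intervals longer than `pause_threshold` are hands-off time and excluded;
# an interval spanning a minute boundary is attributed to the minute
# containing its midpoint.  A minute with no compressions has undefined
# (NA) depth; a minute with no attributable non-pause interval has
# undefined rate.

#' Per-minute depth and rate summaries
#'
#' Reduces an attempt's event stream to one row per analysis minute with the
#' mean compression depth (mm), the instantaneous compression rate
#' (compressions/min during active compression periods) and the compression
#' count.  Events at or beyond the analysis span are ignored.
#'
#' @param record A [cpr_attempt()].
#' @param analysis_minutes Number of minutes analysed (default 12, the first
#'   twelve minutes of the attempt).
#' @param pause_threshold Inter-compression gaps longer than this many
#'   seconds are treated as hands-off time and excluded from the rate
#'   (default 1.5).
#' @param allow_short If the attempt is shorter than the analysis span the
#'   default is an error; with `allow_short = TRUE` only the attempt's
#'   complete minutes are analysed.
#' @return A data frame (class `cpr_minute_summary`) with columns `minute`,
#'   `mean_depth_mm`, `rate_per_min`, `n_compressions`, one row per minute,
#'   and the attempt id in attribute `attempt_id`.  Undefined metrics are
#'   `NA`.
#' @examples
#' rec <- generate_attempt(synthetic_config("ex", depth_baseline_mm = 45,
#'                                          rate_baseline = 100, seed = 1))
#' minute_summaries(rec)
#' @export
minute_summaries <- function(record, analysis_minutes = 12,
                             pause_threshold = 1.5, allow_short = FALSE) {
  validate_cpr_attempt(record)
  if (analysis_minutes < 1) cpr_abort("analysis_minutes must be >= 1")
  if (record$duration_s < 60 * analysis_minutes) {
    if (!allow_short) {
      cpr_abort(sprintf(
        paste0("attempt '%s' lasts %.1f s but %d analysis minutes (%d s) are",
               " required; use allow_short = TRUE to analyse complete minutes only"),
        record$attempt_id, record$duration_s, analysis_minutes,
        60L * analysis_minutes), "cpr_short_attempt_error")
    }
    analysis_minutes <- floor(record$duration_s / 60)
    if (analysis_minutes < 1) {
      cpr_abort(sprintf("attempt '%s' does not cover a single complete minute",
                        record$attempt_id), "cpr_short_attempt_error")
    }
  }
  m <- as.integer(analysis_minutes)
  t <- record$events$time_s
  d <- record$events$depth_mm

  minute_of <- floor(t / 60) + 1
  in_span <- minute_of <= m
  n_comp <- tabulate(minute_of[in_span], nbins = m)

  mean_depth <- rep(NA_real_, m)
  if (any(in_span)) {
    sums <- rowsum(d[in_span], group = minute_of[in_span])
    idx <- as.integer(rownames(sums))
    mean_depth[idx] <- sums[, 1L] / n_comp[idx]
  }

  rate <- rep(NA_real_, m)
  if (length(t) >= 2L) {
    dt <- diff(t)
    mid_minute <- floor((t[-length(t)] + t[-1L]) / 2 / 60) + 1
    keep <- dt <= pause_threshold & mid_minute <= m
    if (any(keep)) {
      isum <- rowsum(dt[keep], group = mid_minute[keep])
      icnt <- rowsum(rep(1, sum(keep)), group = mid_minute[keep])
      idx <- as.integer(rownames(isum))
      rate[idx] <- 60 / (isum[, 1L] / icnt[, 1L])
    }
  }

  out <- data.frame(minute = seq_len(m), mean_depth_mm = mean_depth,
                    rate_per_min = rate, n_compressions = n_comp)
  attr(out, "attempt_id") <- record$attempt_id
  class(out) <- c("cpr_minute_summary", "data.frame")
  out
}

#' Per-minute depth trajectory
#'
#' Reshapes minute summaries to the (minute, mean depth) pairs used for
#' plotting and classification, preserving undefined minutes as `NA` and
#' the minute order.
#'
#' @param summaries Output of [minute_summaries()].
#' @return Data frame with columns `minute` and `mean_depth_mm`.
#' @export
depth_trajectory <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("minute", "mean_depth_mm") %in% names(summaries)))
  out <- data.frame(minute = summaries$minute,
                    mean_depth_mm = summaries$mean_depth_mm)
  out[order(out$minute), , drop = FALSE]
}

#' Cohort-wide minute summary table
#'
#' Stacks [minute_summaries()] for every attempt into one exportable table.
#'
#' @inheritParams minute_summaries
#' @param cohort List of `cpr_attempt` records.
#' @return Data frame with columns `attempt_id`, `minute`, `mean_depth_mm`,
#'   `rate_per_min`, `n_compressions`.
#' @export
minute_summary_table <- function(cohort, analysis_minutes = 12,
                                 pause_threshold = 1.5, allow_short = FALSE) {
  rows <- lapply(cohort, function(rec) {
    s <- minute_summaries(rec, analysis_minutes = analysis_minutes,
                          pause_threshold = pause_threshold,
                          allow_short = allow_short)
    cbind(attempt_id = rec$attempt_id, as.data.frame(s))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
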