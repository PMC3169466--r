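# Hands-off pause detection and no-flow ratio (NFR).
#
# A pause is any maximal interval containing no compression whose length
# exceeds `pause_threshold`, including the leading interval from scenario
# start to the first compression and the trailing interval from the last
# compression to the end of the analysis span.  When a gap exceeds the
# threshold the entire gap counts as hands-off, not just the excess.
# The NFR is hands-off time divided by total time; it is analysed in
# 3-minute windows (0/180/360/540/720 s boundaries, the Norwegian-guideline
# rhythm-check cycle), pauses being split at window boundaries.

#' Detect hands-off pauses
#'
#' @param record A [cpr_attempt()].
#' @param pause_threshold Minimum gap length (s) counted as a pause
#'   (default 1.5; strict inequality — a gap of exactly the threshold is
#'   not a pause).
#' @param analysis_end End of the analysed span in seconds (default 720);
#'   events beyond it are ignored and pauses are clipped to
#'   `[0, analysis_end)`.
#' @return Data frame with columns `start_s`, `end_s`, `duration_s`; zero
#'   rows if compressions are never interrupted.  An attempt with no
#'   compressions before `analysis_end` yields the single pause
#'   `[0, analysis_end)`.
#' @export
detect_pauses <- function(record, pause_threshold = 1.5, analysis_end = 720) {
  validate_cpr_attempt(record)
  t <- record$events$time_s
  t <- t[t < analysis_end]
  bounds_lo <- c(0, t)
  bounds_hi <- c(t, analysis_end)
  len <- bounds_hi - bounds_lo
  keep <- len > pause_threshold
  data.frame(start_s = bounds_lo[keep], end_s = bounds_hi[keep],
             duration_s = len[keep])
}

#' No-flow ratio per three-minute window
#'
#' Computes hands-off seconds and the no-flow ratio in each three-minute
#' window of the 12-minute span, plus the overall ratio.  A pause spanning
#' a window boundary contributes its within-window portion to each window;
#' because the four windows tile the span, the overall ratio equals the
#' mean of the window ratios, and NFR depends only on compression timing,
#' never on depth.
#'
#' @inheritParams detect_pauses
#' @param window_s Window length in seconds (default 180); must divide
#'   `analysis_end`.
#' @return A `cpr_nfr_series`: list with `windows` (data frame `window`,
#'   `start_s`, `end_s`, `hands_off_s`, `nfr`), `total_hands_off_s` and
#'   `overall_nfr`.
#' @examples
#' rec <- generate_attempt(synthetic_config("ex", seed = 1,
#'   pauses = data.frame(start_s = 100, duration_s = 36, cause = "shock")))
#' nfr_series(rec)$overall_nfr
#' @export
nfr_series <- function(record, pause_threshold = 1.5, analysis_end = 720,
                       window_s = 180) {
  if (analysis_end %% window_s != 0) {
    cpr_abort("window_s must divide analysis_end exactly")
  }
  if (record$duration_s < analysis_end) {
    cpr_abort(sprintf("attempt '%s' lasts %.1f s; %g s are required for the NFR",
                      record$attempt_id, record$duration_s, analysis_end),
              "cpr_short_attempt_error")
  }
  pauses <- detect_pauses(record, pause_threshold = pause_threshold,
                          analysis_end = analysis_end)
  k <- analysis_end / window_s
  w_start <- window_s * (seq_len(k) - 1)
  w_end <- w_start + window_s
  hands_off <- vapply(seq_len(k), function(i) {
    sum(pmax(0, pmin(pauses$end_s, w_end[i]) - pmax(pauses$start_s, w_start[i])))
  }, numeric(1L))
  windows <- data.frame(window = seq_len(k), start_s = w_start, end_s = w_end,
                        hands_off_s = hands_off, nfr = hands_off / window_s)
  structure(list(attempt_id = record$attempt_id, windows = windows,
                 total_hands_off_s = sum(hands_off),
                 overall_nfr = sum(hands_off) / analysis_end),
            class = "cpr_nfr_series")
}

#' @export
print.cpr_nfr_series <- function(x, ...) {
  cat(sprintf("<cpr_nfr_series> %s: overall NFR %.1f%% (%.1f s hands-off)\n",
              x$attempt_id, 100 * x$overall_nfr, x$total_hands_off_s))
  cat("  window NFR (%):",
      paste(sprintf("%.1f", 100 * x$windows$nfr), collapse = ", "), "\n")
  invisible(x)
}

#' Cohort no-flow summary
#'
#' Per-attempt no-flow series plus cohort-level arithmetic means per window,
#' overall mean and the range of per-attempt overall ratios.
#'
#' @inheritParams nfr_series
#' @param cohort List of `cpr_attempt` records.
#' @return A `cpr_cohort_nfr`: list with `per_attempt` (data frame
#'   `attempt_id`, `window`, `hands_off_s`, `nfr`), `overall` (data frame
#'   `attempt_id`, `total_hands_off_s`, `overall_nfr`), `window_means`
#'   (length-`k` ratio vector), `overall_mean` and `overall_range`
#'   (`c(min, max)` of per-attempt overall NFR).
#' @export
cohort_nfr <- function(cohort, pause_threshold = 1.5, analysis_end = 720,
                       window_s = 180) {
  if (length(cohort) < 1L) cpr_abort("cohort must contain at least one attempt")
  series <- lapply(cohort, nfr_series, pause_threshold = pause_threshold,
                   analysis_end = analysis_end, window_s = window_s)
  per_attempt <- do.call(rbind, c(lapply(series, function(s) {
    data.frame(attempt_id = s$attempt_id, window = s$windows$window,
               hands_off_s = s$windows$hands_off_s, nfr = s$windows$nfr)
  }), list(make.row.names = FALSE)))
  overall <- data.frame(
    attempt_id = vapply(series, function(s) s$attempt_id, character(1L)),
    total_hands_off_s = vapply(series, function(s) s$total_hands_off_s, numeric(1L)),
    overall_nfr = vapply(series, function(s) s$overall_nfr, numeric(1L)))
  k <- analysis_end / window_s
  nfr_mat <- matrix(per_attempt$nfr, ncol = k, byrow = TRUE,
                    dimnames = list(overall$attempt_id, paste0("w", seq_len(k))))
  structure(list(per_attempt = per_attempt, overall = overall,
                 nfr_matrix = nfr_mat,
                 window_means = colMeans(nfr_mat),
                 overall_mean = mean(overall$overall_nfr),
                 overall_range = range(overall$overall_nfr)),
            class = "cpr_cohort_nfr")
}

#' @export
print.cpr_cohort_nfr <- function(x, ...) {
  cat(sprintf("<cpr_cohort_nfr> %d attempts\n", nrow(x$overall)))
  cat("  window mean NFR (%):",
      paste(sprintf("%.1f", 100 * x$window_means), collapse = ", "), "\n")
  cat(sprintf("  overall mean %.1f%%, range %.1f-%.1f%%\n",
              100 * x$overall_mean, 100 * x$overall_range[1L],
              100 * x$overall_range[2L]))
  invisible(x)
}
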