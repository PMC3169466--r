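# Good / bad / decay quality classification.
#
# Definitions (2005-guideline criteria, assessed per analysis minute):
#   good  - the criterion holds for every minute (depth >= depth_min_mm;
#           rate inside [rate_low, rate_high], boundaries inclusive);
#   bad   - the criterion already fails in minute 1 (the label is fully
#           determined by minute 1, whatever happens later);
#   decay - minute 1 satisfies the criterion but some later minute does not;
#           the onset is the first failing minute.
# An undefined minute metric (no compressions) fails the criterion.
# Depth and rate are classified independently.

#' Guideline thresholds for quality classification
#'
#' @param depth_min_mm Minimum adequate mean compression depth in mm
#'   (default 40, the 2005-guideline floor; set 50 for the 2010 guideline).
#' @param rate_low,rate_high Inclusive bounds of the adequate compression
#'   rate band in compressions/min (default 100-120).
#' @return A `cpr_thresholds` object.
#' @export
cpr_thresholds <- function(depth_min_mm = 40, rate_low = 100, rate_high = 120) {
  if (depth_min_mm <= 0) cpr_abort("depth_min_mm must be positive")
  if (rate_low >= rate_high) cpr_abort("rate_low must be smaller than rate_high")
  structure(list(depth_min_mm = depth_min_mm, rate_low = rate_low,
                 rate_high = rate_high), class = "cpr_thresholds")
}

new_quality_label <- function(dimension, ok) {
  ok[is.na(ok)] <- FALSE
  if (!ok[1L]) {
    label <- "bad"
    onset <- NA_integer_
  } else if (all(ok)) {
    label <- "good"
    onset <- NA_integer_
  } else {
    label <- "decay"
    onset <- which(!ok)[1L]
  }
  structure(list(dimension = dimension, label = label,
                 onset_minute = as.integer(onset)),
            class = "cpr_quality_label")
}

#' @export
print.cpr_quality_label <- function(x, ...) {
  cat(sprintf("<cpr_quality_label> %s: %s%s\n", x$dimension, x$label,
              if (!is.na(x$onset_minute))
                sprintf(" (onset minute %d)", x$onset_minute) else ""))
  invisible(x)
}

check_summaries <- function(summaries, analysis_minutes) {
  if (!is.data.frame(summaries) || nrow(summaries) < analysis_minutes) {
    cpr_abort(sprintf("classification needs %d minute summaries, got %d",
                      analysis_minutes,
                      if (is.data.frame(summaries)) nrow(summaries) else 0L))
  }
  if (summaries$minute[1L] != 1L) cpr_abort("minute 1 summary is missing")
  summaries[seq_len(analysis_minutes), , drop = FALSE]
}

#' Classify compression depth as good, bad or decay
#'
#' Compares each minute's mean depth against `th$depth_min_mm` (exact stored
#' values, `>=` inclusive, no rounding before comparison) and applies the
#' good / bad / decay definitions: bad is determined solely by minute 1,
#' decay requires a compliant minute 1 followed by a failing minute, and the
#' decay onset is the first minute whose mean depth is below the threshold
#' (or undefined).
#'
#' @param summaries Output of [minute_summaries()].
#' @param th A [cpr_thresholds()] object.
#' @param analysis_minutes Number of minutes the classification covers
#'   (default 12); fewer available summaries is an error.
#' @return A `cpr_quality_label` with fields `dimension` (`"depth"`),
#'   `label` and `onset_minute` (`NA` unless `label == "decay"`).
#' @export
classify_depth <- function(summaries, th = cpr_thresholds(),
                           analysis_minutes = 12) {
  s <- check_summaries(summaries, analysis_minutes)
  new_quality_label("depth", s$mean_depth_mm >= th$depth_min_mm)
}

#' Classify compression rate as good, bad or decay
#'
#' As [classify_depth()], for the per-minute instantaneous rate against the
#' inclusive band `[th$rate_low, th$rate_high]`: a rate of exactly 100 or
#' 120/min is adequate; decay covers both slowing below the band and
#' speeding up above it.
#'
#' @inheritParams classify_depth
#' @return A `cpr_quality_label` with `dimension == "rate"`.
#' @export
classify_rate <- function(summaries, th = cpr_thresholds(),
                          analysis_minutes = 12) {
  s <- check_summaries(summaries, analysis_minutes)
  new_quality_label("rate",
                    s$rate_per_min >= th$rate_low & s$rate_per_min <= th$rate_high)
}

#' Classify every attempt in a cohort
#'
#' Runs [minute_summaries()] plus both classifiers on each attempt and
#' tabulates the good/bad/decay group counts per dimension, with
#' percentages rounded to the nearest integer.
#'
#' @inheritParams minute_summaries
#' @param cohort List of `cpr_attempt` records.
#' @param th A [cpr_thresholds()] object.
#' @return A `cpr_cohort_classification`: list with `table` (one row per
#'   attempt: `attempt_id`, `depth_label`, `depth_onset_min`, `rate_label`,
#'   `rate_onset_min`), `depth_counts`, `rate_counts` (named good/bad/decay
#'   vectors summing to `n`), `depth_pct`, `rate_pct` (integer percent) and
#'   `n`.
#' @examples
#' cls <- classify_cohort(reference_cohort())
#' cls$depth_counts
#' @export
classify_cohort <- function(cohort, th = cpr_thresholds(),
                            analysis_minutes = 12, pause_threshold = 1.5,
                            allow_short = FALSE) {
  if (length(cohort) < 1L) cpr_abort("cohort must contain at least one attempt")
  rows <- lapply(cohort, function(rec) {
    res <- tryCatch({
      s <- minute_summaries(rec, analysis_minutes = analysis_minutes,
                            pause_threshold = pause_threshold,
                            allow_short = allow_short)
      list(depth = classify_depth(s, th, analysis_minutes),
           rate = classify_rate(s, th, analysis_minutes))
    }, error = function(e) {
      cpr_abort(sprintf("attempt '%s': %s", rec$attempt_id,
                        conditionMessage(e)), "cpr_cohort_error")
    })
    data.frame(attempt_id = rec$attempt_id,
               depth_label = res$depth$label,
               depth_onset_min = res$depth$onset_minute,
               rate_label = res$rate$label,
               rate_onset_min = res$rate$onset_minute)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  lv <- c("good", "bad", "decay")
  depth_counts <- table(factor(tab$depth_label, levels = lv))
  rate_counts <- table(factor(tab$rate_label, levels = lv))
  n <- nrow(tab)
  structure(list(
    table = tab,
    depth_counts = stats::setNames(as.integer(depth_counts), lv),
    rate_counts = stats::setNames(as.integer(rate_counts), lv),
    depth_pct = stats::setNames(as.integer(round(100 * as.integer(depth_counts) / n)), lv),
    rate_pct = stats::setNames(as.integer(round(100 * as.integer(rate_counts) / n)), lv),
    n = n
  ), class = "cpr_cohort_classification")
}

#' @export
print.cpr_cohort_classification <- function(x, ...) {
  cat(sprintf("<cpr_cohort_classification> %d attempts\n", x$n))
  for (dim in c("depth", "rate")) {
    cnt <- x[[paste0(dim, "_counts")]]
    pct <- x[[paste0(dim, "_pct")]]
    cat(sprintf("  %s: good %d (%d%%), bad %d (%d%%), decay %d (%d%%)\n",
                dim, cnt["good"], pct["good"], cnt["bad"], pct["bad"],
                cnt["decay"], pct["decay"]))
  }
  on_d <- sort(x$table$depth_onset_min[!is.na(x$table$depth_onset_min)])
  on_r <- sort(x$table$rate_onset_min[!is.na(x$table$rate_onset_min)])
  if (length(on_d)) cat("  depth decay onsets (min):", paste(on_d, collapse = ", "), "\n")
  if (length(on_r)) cat("  rate decay onsets (min):", paste(on_r, collapse = ", "), "\n")
  invisible(x)
}
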