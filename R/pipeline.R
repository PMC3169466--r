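# End-to-end orchestration: cohort in, report bundle out.

#' Run the full chest-compression quality analysis
#'
#' Reads a cohort, computes per-minute summaries, good/bad/decay
#' classification, no-flow metrics and (for cohorts of at least two
#' attempts) the no-flow trend statistics, and writes a deterministic
#' report bundle:
#'
#' * `minute_summaries.csv` — `attempt_id, minute, mean_depth_mm,
#'   rate_per_min, n_compressions`
#' * `classification.csv` — `attempt_id, depth_label, depth_onset_min,
#'   rate_label, rate_onset_min`
#' * `nfr_windows.csv` — `attempt_id, window, hands_off_s, nfr`
#' * `nfr_summary.csv` — cohort window means, overall mean and range
#' * `stats.json` — ANOVA + Bonferroni-adjusted pairwise tests
#' * `summary.txt` — human-readable summary (percentages rounded to the
#'   nearest integer; the machine outputs keep full precision)
#' * `run_manifest.json` — configuration echo, its MD5 hash and the
#'   package version
#'
#' Outputs are byte-identical across reruns with the same inputs and
#' configuration.  Any stage failure removes the partial outputs and
#' re-raises the error with the stage named.
#'
#' @param input Manifest file, directory of attempt CSVs, or a list of
#'   `cpr_attempt` records.
#' @param out_dir Output directory (created if needed).
#' @param thresholds A [cpr_thresholds()] object.
#' @param pause_threshold Hands-off gap threshold in seconds.
#' @param analysis_minutes Analysis span in minutes.
#' @param allow_short Analyse complete minutes of short attempts instead of
#'   erroring.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the classification, NFR summary, trend
#'   statistics (or `NULL`) and the written file paths.
#' @export
run_analysis <- function(input, out_dir, thresholds = cpr_thresholds(),
                         pause_threshold = 1.5, analysis_minutes = 12,
                         allow_short = FALSE, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "read"
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    cpr_abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
              "cpr_pipeline_error")
  }
  tryCatch({
    cohort <- if (is.character(input)) read_cohort(input, quiet = quiet) else input
    say("analysing %d attempts", length(cohort))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    emit_csv <- function(df, name) {
      f <- file.path(out_dir, name)
      write.csv(df, f, row.names = FALSE, quote = FALSE)
      written <<- c(written, f)
      f
    }

    stage <- "minute_metrics"
    mtab <- minute_summary_table(cohort, analysis_minutes = analysis_minutes,
                                 pause_threshold = pause_threshold,
                                 allow_short = allow_short)
    emit_csv(mtab, "minute_summaries.csv")

    stage <- "classification"
    cls <- classify_cohort(cohort, th = thresholds,
                           analysis_minutes = analysis_minutes,
                           pause_threshold = pause_threshold,
                           allow_short = allow_short)
    emit_csv(cls$table, "classification.csv")

    stage <- "noflow"
    nfr <- cohort_nfr(cohort, pause_threshold = pause_threshold,
                      analysis_end = 60 * analysis_minutes)
    emit_csv(nfr$per_attempt, "nfr_windows.csv")
    nfr_summary <- data.frame(
      statistic = c(paste0("window_mean_", seq_along(nfr$window_means)),
                    "overall_mean", "overall_min", "overall_max"),
      nfr = c(unname(nfr$window_means), nfr$overall_mean, nfr$overall_range))
    emit_csv(nfr_summary, "nfr_summary.csv")

    stage <- "trend_statistics"
    trend <- NULL
    if (length(cohort) >= 2L) {
      trend <- nfr_trend_analysis(nfr$nfr_matrix)
      f <- file.path(out_dir, "stats.json")
      jsonlite::write_json(trend_report_list(trend), f, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      written <- c(written, f)
    } else {
      warning("fewer than 2 attempts: trend statistics skipped",
              call. = FALSE)
      say("trend statistics skipped (n < 2)")
    }

    stage <- "report"
    config <- list(thresholds = unclass(thresholds),
                   pause_threshold = pause_threshold,
                   analysis_minutes = analysis_minutes,
                   allow_short = allow_short)
    cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
    tmp <- tempfile()
    writeLines(cfg_json, tmp)
    cfg_md5 <- unname(tools::md5sum(tmp))
    unlink(tmp)
    manifest <- list(package = "cprquality",
                     version = as.character(utils::packageVersion("cprquality")),
                     n_attempts = length(cohort), config = config,
                     config_md5 = cfg_md5,
                     files = basename(written))
    f <- file.path(out_dir, "run_manifest.json")
    jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, f)

    txt <- c(
      sprintf("Chest compression quality report (%d attempts)", cls$n),
      "",
      sprintf("Depth: good %d (%d%%), bad %d (%d%%), decay %d (%d%%)",
              cls$depth_counts["good"], cls$depth_pct["good"],
              cls$depth_counts["bad"], cls$depth_pct["bad"],
              cls$depth_counts["decay"], cls$depth_pct["decay"]),
      sprintf("Rate:  good %d (%d%%), bad %d (%d%%), decay %d (%d%%)",
              cls$rate_counts["good"], cls$rate_pct["good"],
              cls$rate_counts["bad"], cls$rate_pct["bad"],
              cls$rate_counts["decay"], cls$rate_pct["decay"]),
      sprintf("NFR window means (%%): %s",
              paste(round(100 * nfr$window_means), collapse = ", ")),
      sprintf("NFR overall mean %d%%, range %d-%d%%",
              round(100 * nfr$overall_mean),
              round(100 * nfr$overall_range[1L]),
              round(100 * nfr$overall_range[2L])),
      if (!is.null(trend)) sprintf(
        "NFR trend: F(%d, %d) = %.2f, p = %.3g; adjusted pairwise level %.4f",
        trend$anova$df_effect, trend$anova$df_error, trend$anova$f_stat,
        trend$anova$p_value, trend$alpha_adjusted)
      else "NFR trend: skipped (fewer than 2 attempts)"
    )
    f <- file.path(out_dir, "summary.txt")
    writeLines(txt, f)
    written <- c(written, f)
    say("report written to %s", out_dir)

    invisible(list(classification = cls, nfr = nfr, trend = trend,
                   files = written))
  }, error = function(e) {
    if (inherits(e, "cpr_pipeline_error")) stop(e) else on_fail(e)
  })
}
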