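# Event-stream I/O.
#
# One CSV per resuscitation attempt.  Layout:
#
#   #attempt_id: A01          <- optional metadata comment lines
#   #duration_s: 720
#   time_s,event_type,depth_mm
#   12.4,compression,43.25
#   13.0,ventilation,
#
# `event_type` is "compression" or "ventilation"; ventilation rows carry an
# empty depth and are skipped on read (the package analyses the compression
# channel only).  Times are seconds from scenario start, '.' decimal
# separator, UTF-8.  Numbers are written with "%.17g" so that a written file
# reads back to bit-identical doubles.

EVENT_HEADER <- c("time_s", "event_type", "depth_mm")

fmt_num <- function(x) sprintf("%.17g", x)

#' Construct a resuscitation attempt record
#'
#' An attempt record holds one resuscitation attempt: an identifier, the
#' ordered compression events (time in seconds from scenario start, peak
#' depth in mm) and the scenario duration.
#'
#' @param attempt_id Non-empty string identifying the attempt.
#' @param time_s Numeric vector of compression times in seconds, strictly
#'   increasing, all `>= 0` and `< duration_s`.
#' @param depth_mm Numeric vector of peak compression depths in mm,
#'   non-negative, same length as `time_s`.
#' @param duration_s Scenario length in seconds (default 720, i.e. the
#'   12-minute analysis span).
#' @return An object of class `cpr_attempt`: a list with elements
#'   `attempt_id`, `events` (data frame with `time_s`, `depth_mm`) and
#'   `duration_s`.
#' @examples
#' cpr_attempt("demo", time_s = c(1, 1.5, 2), depth_mm = c(42, 44, 43))
#' @export
cpr_attempt <- function(attempt_id, time_s = numeric(), depth_mm = numeric(),
                        duration_s = 720) {
  x <- structure(
    list(
      attempt_id = as.character(attempt_id),
      events = data.frame(time_s = as.numeric(time_s),
                          depth_mm = as.numeric(depth_mm)),
      duration_s = as.numeric(duration_s)
    ),
    class = "cpr_attempt"
  )
  validate_cpr_attempt(x)
}

#' Validate an attempt record
#'
#' Checks the `cpr_attempt` invariants: non-empty id, finite non-negative
#' times and depths, strictly increasing times, all times below the
#' scenario duration.  Errors (class `cpr_validation_error`) name the first
#' offending event row.
#'
#' @param x A `cpr_attempt`.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_cpr_attempt <- function(x) {
  if (!inherits(x, "cpr_attempt")) {
    cpr_abort("not a cpr_attempt object")
  }
  if (length(x$attempt_id) != 1L || is.na(x$attempt_id) || !nzchar(x$attempt_id)) {
    cpr_abort("attempt_id must be a single non-empty string")
  }
  if (length(x$duration_s) != 1L || !is.finite(x$duration_s) || x$duration_s <= 0) {
    cpr_abort("duration_s must be a single positive number")
  }
  ev <- x$events
  if (nrow(ev) > 0L) {
    if (anyNA(ev$time_s) || any(!is.finite(ev$time_s)) || any(ev$time_s < 0)) {
      cpr_abort(sprintf("event times must be finite and non-negative (row %d)",
                        which(!is.finite(ev$time_s) | ev$time_s < 0)[1L]))
    }
    if (anyNA(ev$depth_mm) || any(!is.finite(ev$depth_mm)) || any(ev$depth_mm < 0)) {
      cpr_abort(sprintf("compression depths must be finite and non-negative (row %d)",
                        which(!is.finite(ev$depth_mm) | ev$depth_mm < 0)[1L]))
    }
    nondec <- which(diff(ev$time_s) <= 0)
    if (length(nondec) > 0L) {
      cpr_abort(sprintf("event times must be strictly increasing (violated at row %d)",
                        nondec[1L] + 1L))
    }
    if (any(ev$time_s >= x$duration_s)) {
      cpr_abort("all event times must be smaller than duration_s")
    }
  }
  x
}

#' @export
print.cpr_attempt <- function(x, ...) {
  cat(sprintf("<cpr_attempt> %s: %d compressions over %.1f s\n",
              x$attempt_id, nrow(x$events), x$duration_s))
  if (nrow(x$events) > 0L) {
    cat(sprintf("  mean depth %.1f mm, first event at %.2f s, last at %.2f s\n",
                mean(x$events$depth_mm), x$events$time_s[1L],
                x$events$time_s[nrow(x$events)]))
  }
  invisible(x)
}

parse_meta_lines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  meta
}

#' Read one attempt file
#'
#' Reads a compression event stream in the package's CSV dialect (see
#' [write_attempt()]).  Ventilation rows are skipped with a message giving
#' their count.  The reader validates rather than repairs: non-monotone
#' timestamps or negative depths raise a validation error naming the first
#' offending data row; a wrong header raises a format error.
#'
#' @param path Path to the CSV file.
#' @param quiet Suppress the skipped-ventilation message.
#' @return A [cpr_attempt()] record.  If the metadata comment lines are
#'   absent, `attempt_id` defaults to the file name without extension and
#'   `duration_s` to `max(720, last event time + 1)`.
#' @export
read_attempt <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    cpr_abort(sprintf("file '%s' does not exist", path), "cpr_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta <- parse_meta_lines(lines[is_meta])
  body <- lines[!is_meta & nzchar(lines)]
  if (length(body) == 0L) {
    cpr_abort(sprintf("'%s': missing header row", path), "cpr_format_error")
  }
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(header), EVENT_HEADER)) {
    cpr_abort(sprintf("'%s': header must be '%s' (got '%s')", path,
                      paste(EVENT_HEADER, collapse = ","), body[1L]),
              "cpr_format_error")
  }
  df <- if (length(body) > 1L) {
    read.csv(text = body, header = TRUE,
             colClasses = c("numeric", "character", "character"),
             strip.white = TRUE)
  } else {
    data.frame(time_s = numeric(), event_type = character(),
               depth_mm = character())
  }
  bad_type <- !df$event_type %in% c("compression", "ventilation")
  if (any(bad_type)) {
    cpr_abort(sprintf("'%s': unknown event_type '%s' at data row %d", path,
                      df$event_type[bad_type][1L], which(bad_type)[1L]),
              "cpr_format_error")
  }
  n_vent <- sum(df$event_type == "ventilation")
  if (n_vent > 0L && !quiet) {
    message(sprintf("read_attempt: skipped %d ventilation event%s in '%s'",
                    n_vent, if (n_vent == 1L) "" else "s", basename(path)))
  }
  comp <- df[df$event_type == "compression", , drop = FALSE]
  depth <- suppressWarnings(as.numeric(comp$depth_mm))
  if (anyNA(depth) && nrow(comp) > 0L) {
    cpr_abort(sprintf("'%s': non-numeric depth at compression row %d", path,
                      which(is.na(depth))[1L]), "cpr_format_error")
  }
  id <- meta$attempt_id
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  duration <- if (!is.null(meta$duration_s)) as.numeric(meta$duration_s) else
    max(720, if (nrow(comp) > 0L) max(comp$time_s) + 1 else 0)
  cpr_attempt(id, comp$time_s, depth, duration)
}

#' Write one attempt file
#'
#' Writes a [cpr_attempt()] in the package's CSV dialect.  Output is
#' bit-stable: fixed column order, fixed `"%.17g"` number formatting and
#' `"\n"` line endings, so writing the same record twice yields
#' byte-identical files and `read_attempt(write_attempt(x))` returns `x`
#' exactly.
#'
#' @param record A valid `cpr_attempt`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_attempt <- function(record, path) {
  validate_cpr_attempt(record)
  ev <- record$events
  lines <- c(
    sprintf("#attempt_id: %s", record$attempt_id),
    sprintf("#duration_s: %s", fmt_num(record$duration_s)),
    paste(EVENT_HEADER, collapse = ","),
    if (nrow(ev) > 0L) {
      sprintf("%s,compression,%s", fmt_num(ev$time_s), fmt_num(ev$depth_mm))
    }
  )
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) cpr_abort(
                    sprintf("cannot open '%s' for writing: %s", path,
                            conditionMessage(e)), "cpr_io_error"))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a cohort of attempts
#'
#' Reads all attempts named by a manifest file (one path per line, blank
#' lines and `#` comments ignored, relative paths resolved against the
#' manifest's directory) or all `*.csv` files in a directory.  Any
#' single-file failure aborts the whole read with that file named;
#' duplicate attempt ids are rejected.
#'
#' @param path Manifest file or directory.
#' @param quiet Passed to [read_attempt()].
#' @return A list of `cpr_attempt` records (class `cpr_cohort`), sorted by
#'   `attempt_id`.
#' @export
read_cohort <- function(path, quiet = FALSE) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  } else if (file.exists(path)) {
    lines <- trimws(readLines(path, encoding = "UTF-8"))
    lines <- lines[nzchar(lines) & !grepl("^#", lines)]
    base <- dirname(path)
    files <- ifelse(file.exists(lines), lines, file.path(base, lines))
  } else {
    cpr_abort(sprintf("'%s' is neither a file nor a directory", path),
              "cpr_io_error")
  }
  if (length(files) == 0L) {
    cpr_abort("cohort is empty: no attempt files found", "cpr_cohort_error")
  }
  records <- lapply(files, function(f) {
    tryCatch(read_attempt(f, quiet = quiet), error = function(e) {
      cpr_abort(sprintf("failed to read attempt file '%s': %s", f,
                        conditionMessage(e)), "cpr_cohort_error")
    })
  })
  ids <- vapply(records, function(r) r$attempt_id, character(1L))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    cpr_abort(sprintf("duplicate attempt_id in cohort: %s",
                      paste(dup, collapse = ", ")), "cpr_cohort_error")
  }
  as_cpr_cohort(records[order(ids)])
}

as_cpr_cohort <- function(records) {
  structure(records, class = "cpr_cohort")
}

#' @export
print.cpr_cohort <- function(x, ...) {
  cat(sprintf("<cpr_cohort> %d attempts: %s\n", length(x),
              paste(vapply(x, function(r) r$attempt_id, character(1L)),
                    collapse = ", ")))
  invisible(x)
}

#' Write a cohort to a directory
#'
#' Writes one CSV per attempt (named `<attempt_id>.csv`) plus a
#' `manifest.txt` listing the files, readable by [read_cohort()].
#'
#' @param cohort List of `cpr_attempt` records.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(cohort, function(r) {
    f <- file.path(dir, paste0(r$attempt_id, ".csv"))
    write_attempt(r, f)
    paste0(r$attempt_id, ".csv")
  }, character(1L))
  manifest <- file.path(dir, "manifest.txt")
  writeLines(files, manifest)
  invisible(manifest)
}
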