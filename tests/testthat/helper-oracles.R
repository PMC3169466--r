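# Independent brute-force oracles and random-input helpers.  These
# deliberately re-derive each quantity with the most literal possible loop,
# sharing no code with the package internals they check.

# Mean depth per minute window by explicit per-window filtering.
oracle_minute_means <- function(time_s, depth_mm, n_minutes = 12) {
  vapply(seq_len(n_minutes), function(m) {
    in_win <- time_s >= 60 * (m - 1) & time_s < 60 * m
    if (any(in_win)) mean(depth_mm[in_win]) else NA_real_
  }, numeric(1))
}

# Per-minute rate from non-pause intervals, midpoint attribution.
oracle_minute_rates <- function(time_s, pause_threshold = 1.5, n_minutes = 12) {
  out <- rep(NA_real_, n_minutes)
  if (length(time_s) < 2) return(out)
  for (m in seq_len(n_minutes)) {
    gaps <- c()
    for (i in seq_len(length(time_s) - 1)) {
      gap <- time_s[i + 1] - time_s[i]
      mid <- (time_s[i] + time_s[i + 1]) / 2
      if (gap <= pause_threshold && mid >= 60 * (m - 1) && mid < 60 * m) {
        gaps <- c(gaps, gap)
      }
    }
    if (length(gaps)) out[m] <- 60 / mean(gaps)
  }
  out
}

# Total hands-off time by scanning every inter-event gap (plus lead/trail).
oracle_hands_off <- function(time_s, pause_threshold = 1.5, end = 720) {
  t <- time_s[time_s < end]
  if (length(t) == 0) return(end)
  gaps <- c(t[1] - 0, diff(t), end - t[length(t)])
  sum(gaps[gaps > pause_threshold])
}

# Hands-off inside one window, scanning gaps and clipping at the window.
oracle_window_hands_off <- function(time_s, lo, hi, pause_threshold = 1.5,
                                    end = 720) {
  t <- time_s[time_s < end]
  if (length(t) == 0) return(hi - lo)
  starts <- c(0, t)
  ends <- c(t, end)
  total <- 0
  for (i in seq_along(starts)) {
    if (ends[i] - starts[i] > pause_threshold) {
      total <- total + max(0, min(ends[i], hi) - max(starts[i], lo))
    }
  }
  total
}

# Repeated-measures SS decomposition with explicit double loops.
oracle_rm_anova <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  ss_total <- 0; ss_subj <- 0; ss_cond <- 0
  for (i in seq_len(n)) {
    ss_subj <- ss_subj + k * (mean(x[i, ]) - grand)^2
    for (j in seq_len(k)) ss_total <- ss_total + (x[i, j] - grand)^2
  }
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(x[, j]) - grand)^2
  ss_err <- ss_total - ss_subj - ss_cond
  f <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(ss_cond = ss_cond, ss_subj = ss_subj, ss_err = ss_err,
       ss_total = ss_total, f = f,
       p = pf(f, k - 1, (k - 1) * (n - 1), lower.tail = FALSE))
}

# First minute failing a per-minute criterion, by linear scan.
oracle_first_failure <- function(ok) {
  for (m in seq_along(ok)) {
    if (is.na(ok[m]) || !ok[m]) return(m)
  }
  NA_integer_
}

# Random strictly-increasing event stream with occasional long gaps.
random_stream <- function(n = 400, gap_prob = 0.05, end = 720) {
  dt <- ifelse(runif(n) < gap_prob, runif(n, 2, 30), runif(n, 0.4, 0.7))
  t <- cumsum(dt)
  t[t < end]
}

random_attempt <- function(id = "R1", n = 400, gap_prob = 0.05) {
  t <- random_stream(n, gap_prob)
  cpr_attempt(id, t, runif(length(t), 20, 60), duration_s = 725)
}
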