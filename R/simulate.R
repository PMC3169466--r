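# Synthetic compression event-stream generator.
#
# Compressions are laid down sequentially: from the current compression at
# time t the next follows after 60 / rate(t) seconds, where rate(t) is the
# provider's rate model plus per-compression Gaussian noise.  Scheduled
# pauses (patient assessment, defibrillation, rhythm checks, intubation)
# interrupt the stream: a compression is emitted exactly at the pause start
# and another exactly at the pause end, so the analyzer-measured hands-off
# gap equals the scheduled duration exactly.  Depth is the provider's depth
# model plus truncated-at-zero Gaussian noise.
#
# Depth model ("fatigue" decay): depth stays at depth_baseline_mm until the
# decay-onset minute boundary, then declines linearly *from the reference
# depth* (depth_ref_mm, default 40 mm) with the configured negative slope,
# so the onset minute's mean is ref - |slope|/2 and a threshold classifier
# at ref recovers the configured onset minute.  An explicit per-minute
# profile (depth_profile_mm / rate_profile) overrides the parametric model.

#' Synthetic attempt configuration
#'
#' Parameters of one simulated resuscitation attempt.
#'
#' @param attempt_id Attempt identifier.
#' @param duration_s Scenario length in seconds (default 720).
#' @param depth_baseline_mm Provider's baseline mean compression depth (mm).
#' @param depth_noise_sd_mm Per-compression depth noise SD (mm, `>= 0`).
#' @param depth_decay_onset_min Minute (2..) at which depth decay begins, or
#'   `NULL` for no decay.
#' @param depth_decay_slope_mm_per_min Decay slope, `< 0` when an onset is
#'   set (mm per minute).
#' @param depth_ref_mm Reference depth the decay segment starts from
#'   (default 40 mm, the guideline floor); `depth_baseline_mm` must not be
#'   below it when decay is configured.
#' @param depth_profile_mm Optional explicit per-minute mean-depth vector
#'   (length `>= duration_s / 60`) overriding the parametric depth model.
#' @param rate_baseline Baseline compression rate (per minute).
#' @param rate_noise_sd Per-compression rate noise SD (per minute, `>= 0`).
#' @param rate_drift_per_min Linear rate drift (per minute of elapsed time).
#' @param rate_profile Optional explicit per-minute rate vector overriding
#'   the parametric rate model.
#' @param pauses Data frame with columns `start_s`, `duration_s` and
#'   optionally `cause`: the scheduled hands-off intervals, disjoint and
#'   inside `[0, duration_s)`.
#' @param seed Integer RNG seed; generation is deterministic given the seed.
#' @return A `cpr_synth_config` list.
#' @export
synthetic_config <- function(attempt_id,
                             duration_s = 720,
                             depth_baseline_mm = 45,
                             depth_noise_sd_mm = 0,
                             depth_decay_onset_min = NULL,
                             depth_decay_slope_mm_per_min = 0,
                             depth_ref_mm = 40,
                             depth_profile_mm = NULL,
                             rate_baseline = 110,
                             rate_noise_sd = 0,
                             rate_drift_per_min = 0,
                             rate_profile = NULL,
                             pauses = NULL,
                             seed = 1L) {
  if (is.null(pauses)) {
    pauses <- data.frame(start_s = numeric(), duration_s = numeric(),
                         cause = character())
  }
  if (is.null(pauses$cause)) pauses$cause <- rep("pause", nrow(pauses))
  cfg <- structure(list(
    attempt_id = as.character(attempt_id), duration_s = duration_s,
    depth_baseline_mm = depth_baseline_mm,
    depth_noise_sd_mm = depth_noise_sd_mm,
    depth_decay_onset_min = depth_decay_onset_min,
    depth_decay_slope_mm_per_min = depth_decay_slope_mm_per_min,
    depth_ref_mm = depth_ref_mm,
    depth_profile_mm = depth_profile_mm,
    rate_baseline = rate_baseline, rate_noise_sd = rate_noise_sd,
    rate_drift_per_min = rate_drift_per_min, rate_profile = rate_profile,
    pauses = pauses, seed = as.integer(seed)
  ), class = "cpr_synth_config")
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  if (!nzchar(cfg$attempt_id)) cpr_abort("attempt_id must be non-empty")
  if (cfg$duration_s <= 0) cpr_abort("duration_s must be positive")
  if (cfg$depth_noise_sd_mm < 0 || cfg$rate_noise_sd < 0) {
    cpr_abort("noise standard deviations must be non-negative")
  }
  if (!is.null(cfg$depth_decay_onset_min)) {
    if (cfg$depth_decay_onset_min < 2) {
      cpr_abort("depth_decay_onset_min must be >= 2 (minute 1 must comply)")
    }
    if (cfg$depth_decay_slope_mm_per_min >= 0) {
      cpr_abort("depth_decay_slope_mm_per_min must be negative when decay is configured")
    }
    if (cfg$depth_baseline_mm < cfg$depth_ref_mm) {
      cpr_abort("depth_baseline_mm must be >= depth_ref_mm for a decay config")
    }
  }
  n_min <- ceiling(cfg$duration_s / 60)
  for (fld in c("depth_profile_mm", "rate_profile")) {
    pr <- cfg[[fld]]
    if (!is.null(pr)) {
      if (length(pr) < n_min || any(!is.finite(pr)) || any(pr <= 0)) {
        cpr_abort(sprintf("%s must give a positive value for each of %d minutes",
                          fld, n_min))
      }
    }
  }
  p <- cfg$pauses
  if (nrow(p) > 0L) {
    if (any(p$start_s < 0) || any(p$duration_s <= 0) ||
        any(p$start_s + p$duration_s > cfg$duration_s)) {
      cpr_abort("pauses must lie inside [0, duration_s)")
    }
    o <- order(p$start_s)
    ends <- p$start_s[o] + p$duration_s[o]
    if (any(p$start_s[o][-1L] < ends[-length(ends)])) {
      cpr_abort("pauses must be disjoint")
    }
  }
  cfg
}

# Evaluate the RNG-free seed-scoped block: saves and restores .Random.seed.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

minute_value <- function(profile, t) {
  profile[pmin(floor(t / 60) + 1, length(profile))]
}

depth_mean_at <- function(cfg, t) {
  if (!is.null(cfg$depth_profile_mm)) return(minute_value(cfg$depth_profile_mm, t))
  if (is.null(cfg$depth_decay_onset_min)) {
    return(rep(cfg$depth_baseline_mm, length(t)))
  }
  t0 <- 60 * (cfg$depth_decay_onset_min - 1)
  ifelse(t < t0, cfg$depth_baseline_mm,
         pmax(5, cfg$depth_ref_mm +
                cfg$depth_decay_slope_mm_per_min * (t - t0) / 60))
}

rate_mean_at <- function(cfg, t) {
  if (!is.null(cfg$rate_profile)) return(minute_value(cfg$rate_profile, t))
  cfg$rate_baseline + cfg$rate_drift_per_min * t / 60
}

#' Generate one synthetic attempt
#'
#' Simulates a compression event stream from a [synthetic_config()]:
#' sequential compressions at the configured instantaneous rate, scheduled
#' hands-off pauses, and per-compression depth noise.  Deterministic given
#' the config's seed.
#'
#' @param config A `cpr_synth_config`.
#' @return A [cpr_attempt()].
#' @examples
#' rec <- generate_attempt(synthetic_config("sim1", depth_baseline_mm = 45,
#'                                          rate_baseline = 110, seed = 7))
#' rec
#' @export
generate_attempt <- function(config) {
  validate_synth_config(config)
  with_seed(config$seed, {
    p <- config$pauses[order(config$pauses$start_s), , drop = FALSE]
    p_start <- p$start_s
    p_end <- p$start_s + p$duration_s
    np <- length(p_start)
    dur <- config$duration_s
    times <- numeric(ceiling(dur * 4))  # generous preallocation
    n <- 0L
    emit <- function(tt) {
      n <<- n + 1L
      times[n] <<- tt
    }
    t <- 0
    i <- 1L
    repeat {
      r <- rate_mean_at(config, t)
      if (config$rate_noise_sd > 0) r <- r + rnorm(1L, 0, config$rate_noise_sd)
      delta <- 60 / max(40, r)
      tn <- t + delta
      if (i <= np && tn >= p_start[i]) {
        if (p_start[i] > t + 1e-9) emit(p_start[i])
        t <- p_end[i]
        i <- i + 1L
        if (t >= dur) break
        emit(t)
      } else if (tn >= dur) {
        break
      } else {
        emit(tn)
        t <- tn
      }
    }
    if (n == 0L) {
      cpr_abort("infeasible schedule: no compressions fit inside the scenario",
                "cpr_generator_error")
    }
    times <- times[seq_len(n)]
    depth <- depth_mean_at(config, times)
    if (config$depth_noise_sd_mm > 0) {
      depth <- pmax(0, depth + rnorm(n, 0, config$depth_noise_sd_mm))
    }
    cpr_attempt(config$attempt_id, times, depth, dur)
  })
}

#' Generate a synthetic cohort
#'
#' One attempt per config.  When `master_seed` is given, each config's seed
#' is replaced by an independent sub-seed derived from it, so regenerating
#' with the same master seed reproduces the cohort exactly and changing one
#' attempt's sub-seed leaves the others untouched.
#'
#' @param configs List of [synthetic_config()] objects with distinct ids.
#' @param master_seed Optional integer master seed.
#' @return A `cpr_cohort` list of attempts.
#' @export
generate_cohort <- function(configs, master_seed = NULL) {
  if (length(configs) < 1L) cpr_abort("need at least one config")
  ids <- vapply(configs, function(cf) cf$attempt_id, character(1L))
  if (anyDuplicated(ids)) cpr_abort("attempt ids must be distinct")
  if (!is.null(master_seed)) {
    configs <- lapply(seq_along(configs), function(i) {
      cf <- configs[[i]]
      cf$seed <- as.integer((master_seed + 7919 * i) %% 2147483647L)
      cf
    })
  }
  as_cpr_cohort(lapply(configs, generate_attempt))
}
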