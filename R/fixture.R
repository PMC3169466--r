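# Fixed-seed 19-attempt reference cohort.
#
# A synthetic stand-in for a 19-provider ALS manikin cohort, used by the
# worked examples and the end-to-end tests.  Its *group structure* mirrors
# the published cohort the package's definitions come from: depth groups
# 5 good / 9 bad / 5 decay with decay onsets at minutes 2, 4, 8, 11 and 12
# and one bad attempt reaching adequate depth only during minutes 3-8;
# rate groups 6 good / 6 bad / 7 decay with exactly one rate-decay onset in
# the first five minutes, two rate-bad attempts correcting after minute 1
# and five attempts starting above 120/min; window NFR means of 22/22/14/10
# percent, overall 17 percent, per-attempt overall NFR from 10 to 32
# percent.  Everything finer than that structure (the per-minute profile
# values, pause-duration splits, noise levels) is invented: these are
# hand-chosen tuning constants, not measured data.
#
# Scenario narrative behind the pause schedule: initial patient assessment
# from t = 0; one defibrillation near t = 60 s (the first shock, after
# which the patient is in PEA so no further charging); a ventilation-
# related interruption near t = 130 s; rhythm checks at 180, 360 and 540 s
# (3-minute cycles); an intubation-related pause near t = 285 s, after
# which interruptions shrink because compressions can continue through
# ventilations.  Each attempt uses the same shape scaled by a per-attempt
# hands-off factor.

FIXTURE_MASTER_SEED <- 20110809L

# Per-minute mean depth (mm), one row per attempt, minutes 1..12.
fixture_depth_profiles <- function() {
  rbind(
    A01 = c(46, 46, 45.5, 45.5, 45, 45, 44.5, 44.5, 44, 44, 43.5, 43.5),
    A02 = c(48, 47.8, 47.6, 47.4, 47.2, 47, 46.8, 46.6, 46.4, 46.2, 46, 45.8),
    A03 = c(44.5, 44.3, 44.1, 43.9, 43.7, 43.5, 43.3, 43.1, 42.9, 42.7, 42.5, 42.3),
    A04 = c(50, 49.7, 49.4, 49.1, 48.8, 48.5, 48.2, 47.9, 47.6, 47.3, 47, 46.7),
    A05 = c(43.5, 43.4, 43.3, 43.2, 43.1, 43, 42.9, 42.8, 42.7, 42.6, 42.5, 42.4),
    A06 = c(36, 38, 41.5, 42.5, 43, 43, 42.5, 41.5, 38, 37, 36.5, 36),
    A07 = c(34, 34, 33.5, 33.5, 33, 33, 32.5, 32.5, 32, 32, 31.5, 31.5),
    A08 = c(37.5, 37.3, 37, 36.8, 36.5, 36.3, 36, 35.8, 35.5, 35.3, 35, 34.8),
    A09 = c(32, 31.8, 31.6, 31.4, 31.2, 31, 30.8, 30.6, 30.4, 30.2, 30, 29.8),
    A10 = c(38, 37.8, 37.6, 37.4, 37.2, 37, 36.8, 36.6, 36.4, 36.2, 36, 35.8),
    A11 = c(36, 35.7, 35.4, 35.1, 34.8, 34.5, 34.2, 33.9, 33.6, 33.3, 33, 32.7),
    A12 = c(30, 30, 30, 29.8, 29.8, 29.8, 29.6, 29.6, 29.6, 29.4, 29.4, 29.4),
    A13 = c(38.5, 38.3, 38.1, 37.9, 37.7, 37.5, 37.3, 37.1, 36.9, 36.7, 36.5, 36.3),
    A14 = c(33, 33, 32.8, 32.8, 32.6, 32.6, 32.4, 32.4, 32.2, 32.2, 32, 32),
    A15 = c(41.5, 38, 36.5, 36, 35.5, 35, 35, 34.5, 34.5, 34, 34, 33.5),
    A16 = c(43, 42, 41.5, 38, 37, 36.5, 36, 35.5, 35, 35, 34.5, 34),
    A17 = c(45, 44.5, 44, 43.5, 43, 42.5, 41.5, 38, 37, 36.5, 36, 35.5),
    A18 = c(44, 43.5, 43, 42.5, 42, 42, 41.5, 41.5, 41.5, 41.5, 38, 37),
    A19 = c(46, 45.5, 45, 44.5, 44, 43.5, 43, 42.5, 42, 41.5, 41.5, 38)
  )
}

# Per-minute compression rate (per minute), minutes 1..12.
fixture_rate_profiles <- function() {
  rbind(
    A01 = c(112, 112, 111, 111, 110, 110, 109, 109, 108, 108, 107, 107),
    A02 = c(125, 112, 111, 111, 110, 110, 109, 109, 108, 108, 107, 107),
    A03 = c(112, 114, 117, 122.5, 124, 125, 125.5, 126, 126, 126.5, 127, 127),
    A04 = c(108, 107, 106, 104, 103, 97.5, 96, 95, 94.5, 94, 93.5, 93),
    A05 = c(110, 109, 107, 105, 104, 102.5, 97.5, 96, 95, 95, 94, 94),
    A06 = c(110, 110, 110, 109, 109, 109, 108, 108, 108, 107, 107, 107),
    A07 = c(128, 114, 112, 111, 110, 110, 109, 108, 108, 107, 107, 106),
    A08 = c(115, 114, 114, 113, 113, 112, 112, 111, 111, 110, 110, 109),
    A09 = c(94, 94, 94.5, 94.5, 95, 95, 95, 94.5, 94.5, 94, 94, 94),
    A10 = c(115, 116, 116.5, 117, 117, 117.5, 117.5, 117.5, 122.5, 123, 124, 124),
    A11 = c(124, 124, 123.5, 123.5, 123, 123, 123, 123.5, 123.5, 124, 124, 124),
    A12 = c(106, 105, 104, 104, 103, 103, 102.5, 102.5, 102.5, 97.5, 96, 95),
    A13 = c(123, 123, 123, 123.5, 123.5, 123.5, 124, 124, 124, 124.5, 124.5, 124.5),
    A14 = c(126, 125.5, 125, 125, 124.5, 124.5, 124, 124, 123.5, 123.5, 123, 123),
    A15 = c(108, 108, 108.5, 108.5, 109, 109, 109, 108.5, 108.5, 108, 108, 108),
    A16 = c(112, 111, 110, 110, 109, 108, 107, 106, 105, 104, 103, 97.5),
    A17 = c(114, 114, 113.5, 113.5, 113, 113, 112.5, 112.5, 112, 112, 111.5, 111.5),
    A18 = c(113, 114, 115, 116, 116.5, 117, 117.5, 122.5, 123, 123.5, 124, 124),
    A19 = c(109, 109, 109, 108.5, 108.5, 108, 108, 107.5, 107.5, 107, 107, 106.5)
  )
}

# Per-attempt hands-off scale factor.  1.0 corresponds to window hands-off
# targets of 39.6 / 39.6 / 25.2 / 18 s (window NFR 22 / 22 / 14 / 10 %);
# the factors average 1 so the cohort means hit those targets, and the
# extremes 0.588235 and 1.882353 give overall NFRs of 10 % and 32 %.
fixture_nfr_scale <- function() {
  c(A01 = 0.99, A02 = 0.83, A03 = 1.10, A04 = 0.64, A05 = 1.21,
    A06 = 1.882353, A07 = 0.90, A08 = 0.70, A09 = 1.28, A10 = 0.96,
    A11 = 1.359412, A12 = 0.86, A13 = 0.588235, A14 = 1.02, A15 = 0.75,
    A16 = 1.15, A17 = 0.93, A18 = 1.06, A19 = 0.79)
}

# Pause schedule for attempt index i with hands-off scale factor `scale`.
# Durations are rounded to 0.1 s; the split fractions vary a little across
# attempts so no two schedules are exact multiples of each other.
fixture_pause_schedule <- function(scale, i) {
  w <- scale * c(39.6, 39.6, 25.2, 18)
  fa <- 0.40 + 0.01 * ((i %% 5) - 2)
  fs <- 0.35 + 0.005 * ((i %% 3) - 1)
  fr <- 0.55 + 0.01 * ((i %% 4) - 1.5)
  assess <- round(fa * w[1L], 1)
  shock <- round(fs * w[1L], 1)
  vent <- round(w[1L] - assess - shock, 1)
  rhythm1 <- round(fr * w[2L], 1)
  intub <- round(w[2L] - rhythm1, 1)
  rhythm2 <- round(w[3L], 1)
  rhythm3 <- round(w[4L], 1)
  data.frame(
    start_s = c(0, 60, 130, 180, 285, 360, 540),
    duration_s = c(assess, shock, vent, rhythm1, intub, rhythm2, rhythm3),
    cause = c("assessment", "defibrillation", "ventilation", "rhythm_check",
              "intubation", "rhythm_check", "rhythm_check")
  )
}

# Internal: the 19 synthetic configs behind reference_cohort().
reference_configs <- function() {
  depth <- fixture_depth_profiles()
  rate <- fixture_rate_profiles()
  scale <- fixture_nfr_scale()
  lapply(seq_len(nrow(depth)), function(i) {
    id <- rownames(depth)[i]
    synthetic_config(
      attempt_id = id,
      duration_s = 720,
      depth_profile_mm = depth[i, ],
      depth_noise_sd_mm = 1.2,
      rate_profile = rate[i, ],
      rate_noise_sd = 3,
      pauses = fixture_pause_schedule(scale[[id]], i),
      seed = i  # replaced by a master-seed-derived sub-seed
    )
  })
}

#' Fixed-seed 19-attempt reference cohort
#'
#' Generates the package's shipped synthetic reference cohort: 19 simulated
#' 12-minute ALS attempts whose good/bad/decay group structure, decay-onset
#' minutes and no-flow-ratio trajectory match the cohort structure the
#' package's quality definitions were built around (see the package
#' vignette).  All finer detail — individual minute profiles, pause splits,
#' noise — is invented and hand-tuned; this is synthetic data, not a
#' measurement record.
#'
#' Regenerating with the same master seed yields identical attempts (and,
#' via [write_cohort()], byte-identical files).
#'
#' @param master_seed Integer master seed; the documented default is
#'   20110809.
#' @return A `cpr_cohort` of 19 [cpr_attempt()] records.
#' @examples
#' coh <- reference_cohort()
#' classify_cohort(coh)
#' @export
reference_cohort <- function(master_seed = FIXTURE_MASTER_SEED) {
  generate_cohort(reference_configs(), master_seed = master_seed)
}
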