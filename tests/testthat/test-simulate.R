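# Synthetic generator: determinism, generator/analyzer consistency,
# parameter recovery.

test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config("det", depth_baseline_mm = 45, depth_noise_sd_mm = 1,
                          rate_baseline = 110, rate_noise_sd = 3, seed = 123,
                          pauses = data.frame(start_s = c(0, 200),
                                              duration_s = c(15, 20),
                                              cause = c("assessment", "check")))
  a <- generate_attempt(cfg)
  b <- generate_attempt(cfg)
  expect_identical(a$events, b$events)
  # and the files are byte-identical
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_attempt(a, f1); write_attempt(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_attempt(synthetic_config("rng", seed = 7,
                                              depth_noise_sd_mm = 2)))
  expect_identical(.Random.seed, before)
})

test_that("noise-free constant configs analyse back to their parameters", {
  cfg <- synthetic_config("clean", depth_baseline_mm = 45, rate_baseline = 110,
                          seed = 1)
  rec <- generate_attempt(cfg)
  s <- minute_summaries(rec)
  expect_equal(s$mean_depth_mm, rep(45, 12))      # exactly the baseline
  expect_equal(s$rate_per_min, rep(110, 12), tolerance = 1e-9)
  expect_identical(classify_depth(s)$label, "good")
  expect_identical(classify_rate(s)$label, "good")
  expect_equal(nfr_series(rec)$overall_nfr, 0)
})

test_that("scheduled pauses come back from the analyzer exactly", {
  pauses <- data.frame(start_s = c(0, 60, 180, 360, 540),
                       duration_s = c(18, 15, 22, 14, 10),
                       cause = "x")
  cfg <- synthetic_config("pex", rate_baseline = 110, seed = 4,
                          pauses = pauses)
  rec <- generate_attempt(cfg)
  p <- detect_pauses(rec)
  expect_equal(p$start_s, pauses$start_s)
  expect_equal(p$duration_s, pauses$duration_s)
  expect_equal(nfr_series(rec)$total_hands_off_s, sum(pauses$duration_s))
})

test_that("parametric decay drops from the reference at the onset minute", {
  cfg <- synthetic_config("dec", depth_baseline_mm = 45,
                          depth_decay_onset_min = 8,
                          depth_decay_slope_mm_per_min = -2, seed = 1)
  s <- minute_summaries(generate_attempt(cfg))
  expect_equal(s$mean_depth_mm[1:7], rep(45, 7))
  expect_equal(s$mean_depth_mm[8], 39, tolerance = 0.05)  # 40 - |slope|/2
  lab <- classify_depth(s)
  expect_identical(lab$label, "decay")
  expect_identical(lab$onset_minute, 8L)
})

test_that("the classifier recovers the configured decay onset under noise", {
  # onset 8, slope -2 mm/min, noise sd 0.5: exact recovery nearly always
  hits <- 0L
  for (seed in 1:200) {
    cfg <- synthetic_config("rec", depth_baseline_mm = 45,
                            depth_noise_sd_mm = 0.5,
                            depth_decay_onset_min = 8,
                            depth_decay_slope_mm_per_min = -2, seed = seed)
    lab <- classify_depth(minute_summaries(generate_attempt(cfg)))
    if (lab$label == "decay" && lab$onset_minute == 8L) hits <- hits + 1L
  }
  expect_gte(hits, 190L)  # >= 95% of 200 seeds

  # shallower slope (1 mm/min), more noise (1 mm): within +/- 1 minute
  near <- 0L
  for (seed in 1:100) {
    cfg <- synthetic_config("rec2", depth_baseline_mm = 44,
                            depth_noise_sd_mm = 1,
                            depth_decay_onset_min = 6,
                            depth_decay_slope_mm_per_min = -1, seed = seed)
    lab <- classify_depth(minute_summaries(generate_attempt(cfg)))
    if (lab$label == "decay" && abs(lab$onset_minute - 6L) <= 1L) {
      near <- near + 1L
    }
  }
  expect_gte(near, 95L)
})

test_that("cohort generation derives independent per-attempt sub-seeds", {
  mk <- function(ids) lapply(ids, function(id) {
    synthetic_config(id, depth_noise_sd_mm = 1, rate_noise_sd = 2, seed = 1)
  })
  c1 <- generate_cohort(mk(c("a", "b", "c")), master_seed = 11)
  c2 <- generate_cohort(mk(c("a", "b", "c")), master_seed = 11)
  expect_identical(c1[[2]]$events, c2[[2]]$events)  # stable across runs
  # changing the master seed changes attempts...
  c3 <- generate_cohort(mk(c("a", "b", "c")), master_seed = 12)
  expect_false(identical(c1[[1]]$events, c3[[1]]$events))
  # ...but attempt i only depends on its own sub-seed: same position, same
  # config, same master seed, regardless of what the neighbours are
  c4 <- generate_cohort(mk(c("a", "zzz", "c")), master_seed = 11)
  expect_identical(c1[[3]]$events, c4[[3]]$events)

  expect_error(generate_cohort(mk(c("a", "a"))), "distinct")
})

test_that("an all-pause schedule is rejected as infeasible", {
  cfg <- synthetic_config("full", duration_s = 100,
                          pauses = data.frame(start_s = 0, duration_s = 100,
                                              cause = "x"))
  expect_error(generate_attempt(cfg), "infeasible",
               class = "cpr_generator_error")
})

test_that("the reference cohort regenerates identically from its seed", {
  c1 <- reference_cohort()
  c2 <- reference_cohort()
  for (i in seq_along(c1)) expect_identical(c1[[i]]$events, c2[[i]]$events)
  expect_length(c1, 19L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1[1:2], d1)
  write_cohort(c2[1:2], d2)
  expect_identical(tools::md5sum(list.files(d1, full.names = TRUE))[[1]],
                   tools::md5sum(list.files(d2, full.names = TRUE))[[1]])
})
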