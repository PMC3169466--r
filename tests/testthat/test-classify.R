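# Good / bad / decay classification: definitions, boundaries, invariants.

summaries_from <- function(depth = rep(45, 12),
                           rate = rep(110, length(depth))) {
  structure(data.frame(minute = seq_along(depth), mean_depth_mm = depth,
                       rate_per_min = rate,
                       n_compressions = ifelse(is.na(depth), 0L, 100L)),
            class = c("cpr_minute_summary", "data.frame"))
}

test_that("depth classification follows the printed definitions", {
  th <- cpr_thresholds()

  # all minutes >= 40 -> good
  lab <- classify_depth(summaries_from(depth = rep(45, 12)), th)
  expect_identical(lab$label, "good")
  expect_true(is.na(lab$onset_minute))

  # compliant start, drops below 40 at minute 4 -> decay, onset 4
  lab <- classify_depth(summaries_from(
    depth = c(42, 41, 40, 39.5, 38, 37, 36, 36, 35, 35, 34, 34)), th)
  expect_identical(lab$label, "decay")
  expect_identical(lab$onset_minute, 4L)

  # sub-threshold minute 1 stays bad even if minutes 3-8 reach >= 40
  lab <- classify_depth(summaries_from(
    depth = c(35, 37, 41, 42, 43, 43, 42, 41, 38, 37, 36, 36)), th)
  expect_identical(lab$label, "bad")
  expect_true(is.na(lab$onset_minute))

  # boundary: exactly 40.0 satisfies ">= 40"
  lab <- classify_depth(summaries_from(depth = rep(40, 12)), th)
  expect_identical(lab$label, "good")

  # undefined minute 1 -> bad; undefined later minute -> decay there
  d <- rep(45, 12); d[1] <- NA
  expect_identical(classify_depth(summaries_from(depth = d), th)$label, "bad")
  d <- rep(45, 12); d[7] <- NA
  lab <- classify_depth(summaries_from(depth = d), th)
  expect_identical(lab$label, "decay")
  expect_identical(lab$onset_minute, 7L)
})

test_that("rate classification uses the inclusive 100-120 band", {
  th <- cpr_thresholds()
  expect_identical(classify_rate(summaries_from(rate = rep(110, 12)))$label,
                   "good")
  expect_identical(classify_rate(summaries_from(rate = rep(100, 12)))$label,
                   "good")  # boundaries inclusive
  expect_identical(classify_rate(summaries_from(rate = rep(120, 12)))$label,
                   "good")

  # minute-1 rate 125 -> bad (too fast at start)
  r <- c(125, rep(110, 11))
  expect_identical(classify_rate(summaries_from(rate = r))$label, "bad")

  # in-band minutes 1-5, 122 at minute 6 -> decay with onset 6
  r <- c(rep(105, 5), 122, rep(122, 6))
  lab <- classify_rate(summaries_from(rate = r))
  expect_identical(lab$label, "decay")
  expect_identical(lab$onset_minute, 6L)

  # slowing below 100 is decay too
  r <- c(rep(110, 8), rep(95, 4))
  lab <- classify_rate(summaries_from(rate = r))
  expect_identical(lab$label, "decay")
  expect_identical(lab$onset_minute, 9L)
})

test_that("too few minute summaries is an error", {
  s <- summaries_from(depth = rep(45, 8))
  expect_error(classify_depth(s), "12")
  expect_silent(classify_depth(s, analysis_minutes = 8))
})

test_that("labels partition the cohort and onsets match a linear scan", {
  set.seed(31)
  th <- cpr_thresholds()
  for (rep in 1:200) {
    depth <- runif(12, 30, 50)
    rate <- runif(12, 90, 130)
    if (runif(1) < 0.1) depth[sample(12, 1)] <- NA
    s <- summaries_from(depth = depth, rate = rate)
    labs <- list(classify_depth(s, th), classify_rate(s, th))
    oks <- list(!is.na(depth) & depth >= 40,
                !is.na(rate) & rate >= 100 & rate <= 120)
    for (i in 1:2) {
      lab <- labs[[i]]
      expect_true(lab$label %in% c("good", "bad", "decay"))
      first_fail <- oracle_first_failure(oks[[i]])
      if (is.na(first_fail)) {
        expect_identical(lab$label, "good")
      } else if (first_fail == 1L) {
        expect_identical(lab$label, "bad")
      } else {
        expect_identical(lab$label, "decay")
        expect_identical(lab$onset_minute, first_fail)
      }
      # onset present iff decay
      expect_identical(lab$label == "decay", !is.na(lab$onset_minute))
    }
  }
})

test_that("bad depends only on minute 1, whatever later minutes do", {
  set.seed(17)
  for (rep in 1:50) {
    depth <- c(runif(1, 30, 39.9), runif(11, 30, 55))
    s1 <- summaries_from(depth = depth)
    s2 <- summaries_from(depth = c(depth[1], sample(depth[-1])))
    expect_identical(classify_depth(s1)$label, "bad")
    expect_identical(classify_depth(s2)$label, "bad")
  }
})

test_that("raising the depth threshold moves labels only toward worse", {
  rank <- c(good = 1, decay = 2, bad = 3)
  set.seed(23)
  for (rep in 1:100) {
    depth <- runif(12, 35, 55)
    s <- summaries_from(depth = depth)
    l40 <- classify_depth(s, cpr_thresholds(depth_min_mm = 40))
    l45 <- classify_depth(s, cpr_thresholds(depth_min_mm = 45))
    l50 <- classify_depth(s, cpr_thresholds(depth_min_mm = 50))
    expect_true(rank[l45$label] >= rank[l40$label])
    expect_true(rank[l50$label] >= rank[l45$label])
  }
})

test_that("classify_cohort tabulates counts that sum to the cohort size", {
  t <- seq(0.5, 720 - 1e-9, by = 0.5)
  good <- cpr_attempt("g", t, rep(45, length(t)), 720)
  cls <- classify_cohort(list(good))
  expect_identical(unname(cls$depth_counts), c(1L, 0L, 0L))
  expect_identical(unname(cls$rate_counts), c(1L, 0L, 0L))
  expect_identical(sum(cls$depth_counts), cls$n)

  # errors carry the attempt id
  short <- cpr_attempt("shorty", c(1, 2), c(40, 41), duration_s = 100)
  expect_error(classify_cohort(list(good, short)), "shorty",
               class = "cpr_cohort_error")
})
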