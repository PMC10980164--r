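hyp <- function(...) new_hypnogram(c(...))

test_that("bouts are the maximal-run partition of the hypnogram", {
  b <- detect_bouts(hyp("N", "N", "W", "R"))
  expect_equal(b$state, c("N", "W", "R"))
  expect_equal(b$duration_s, c(5, 2.5, 2.5))
  expect_equal(nrow(detect_bouts(hyp(rep("N", 10)))), 1)
  # reconstruction: concatenating runs yields the hypnogram
  set.seed(1)
  h <- random_hypnogram(500)
  b <- detect_bouts(h)
  expect_identical(rep(b$state, b$end_epoch - b$start_epoch + 1L),
                   as.character(h))
})

test_that("microarousal rules: duration bound inclusive, NREM flanking required", {
  # exactly 20 s (8 epochs) flanked by N -> one MA
  h <- hyp("N", "N", rep("W", 8), "N")
  ma <- detect_microarousals(h)
  expect_equal(nrow(ma), 1)
  expect_equal(ma$duration_s, 20)
  # 22.5 s (9 epochs) is an ordinary wake bout
  expect_equal(nrow(detect_microarousals(hyp("N", rep("W", 9), "N"))), 0)
  # wake run at the recording edge does not qualify
  expect_equal(nrow(detect_microarousals(hyp(rep("W", 4), "N", "N"))), 0)
  # REM-flanked wake run does not qualify
  expect_equal(nrow(detect_microarousals(hyp("R", rep("W", 4), "N"))), 0)
  # rate is per hour of NREM time
  h2 <- hyp(rep("N", 100), "W", "W", rep("N", 100))
  ma2 <- detect_microarousals(h2)
  expect_equal(attr(ma2, "rate_per_h_nrem"), 1 / (200 * 2.5 / 3600))
})

test_that("consolidated NREM bouts bridge MAs and enforce the 120 s minimum", {
  # N(60) W(10) N(70): one bridged bout spanning 140 s
  h <- hyp(rep("N", 24), rep("W", 4), rep("N", 28))
  cb <- consolidate_nrem(h)
  expect_equal(nrow(cb), 1)
  expect_equal(cb$span_s, 140)
  expect_equal(cb$n_ma, 1)
  # N(60) W(30) N(70): wake too long to bridge, both fragments short
  h2 <- hyp(rep("N", 24), rep("W", 12), rep("N", 28))
  expect_equal(nrow(consolidate_nrem(h2)), 0)
  # N(130) alone
  cb3 <- consolidate_nrem(hyp(rep("N", 52)))
  expect_equal(cb3$span_s, 130)
  expect_equal(cb3$n_ma, 0)
  # REM terminates a span even between long N runs
  h4 <- hyp(rep("N", 50), "R", rep("N", 50))
  expect_equal(consolidate_nrem(h4)$span_s, c(125, 125))
})

test_that("architecture statistics match brute-force oracles on random hypnograms", {
  set.seed(7)
  for (i in 1:60) {
    h <- random_hypnogram(sample(30:300, 1))
    st <- as.character(h)
    b <- detect_bouts(h)
    ob <- oracle_bouts(st)
    expect_equal(b$state, ob$state)
    expect_equal(b$duration_s, ob$duration_s)
    ma <- detect_microarousals(h)
    oma <- oracle_mas(st)
    expect_equal(nrow(ma), if (is.null(oma)) 0L else nrow(oma))
    if (!is.null(oma)) expect_equal(ma$start_s, oma$start_s)
    cb <- consolidate_nrem(h)
    ocb <- oracle_consolidated(st)
    expect_equal(nrow(cb), if (is.null(ocb)) 0L else nrow(ocb))
    if (!is.null(ocb)) {
      expect_equal(cb$start_s, ocb$start_s)
      expect_equal(cb$span_s, ocb$span_s)
    }
    p <- state_percentages(h)
    expect_equal(sum(p), 100)
    expect_equal(unname(p["N"]), 100 * mean(st == "N"))
  }
})

test_that("raising the MA duration bound weakly increases MA and bridged counts", {
  set.seed(21)
  for (i in 1:20) {
    h <- random_hypnogram(200)
    n1 <- nrow(detect_microarousals(h, max_dur_s = 10))
    n2 <- nrow(detect_microarousals(h, max_dur_s = 20))
    expect_gte(n2, n1)
    s1 <- sum(consolidate_nrem(h, ma_max_s = 10)$span_s)
    s2 <- sum(consolidate_nrem(h, ma_max_s = 20)$span_s)
    expect_gte(s2, s1)
  }
})

test_that("episode statistics and duration distributions", {
  b <- data.frame(state = c("N", "N", "W"), duration_s = c(60, 120, 30))
  es <- episode_stats(b, "N", total_hours = 1)
  expect_equal(es$mean_duration_s, 90)
  expect_equal(es$frequency_per_h, 2)
  er <- episode_stats(b, "R", total_hours = 2)
  expect_true(is.nan(er$mean_duration_s))
  expect_equal(er$frequency_per_h, 0)
  d <- data.frame(state = rep("N", 3), duration_s = c(10, 10, 200))
  expect_equal(bout_duration_distribution(d, "N", c(0, 64, Inf)),
               c(2 / 3, 1 / 3))
  expect_equal(bout_duration_distribution(d, "R", c(0, 64, Inf)), c(0, 0))
})

test_that("object-recognition metrics follow the printed formulas", {
  m <- sor_metrics(30, 10)
  expect_equal(m$preference_pct, 75)
  expect_equal(m$discrimination_ratio, 0.5)
  expect_false(m$excluded)
  m2 <- sor_metrics(10, 10)
  expect_equal(m2$preference_pct, 50)
  expect_equal(m2$discrimination_ratio, 0)
  expect_true(sor_metrics(0.5, 1.0)$excluded)
  m3 <- sor_metrics(0, 0)
  expect_true(m3$excluded)
  expect_true(is.nan(m3$preference_pct))
})
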