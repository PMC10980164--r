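test_that("spindle spectrogram bin count and burst localization", {
  expect_equal(nrow(spindle_spectrogram(rnorm(1000), 1000)$power), 5)
  expect_error(spindle_spectrogram(rnorm(100), 1000), "shorter")
  spg0 <- spindle_spectrogram(rep(0, 2000), 1000)
  expect_true(all(spg0$power == 0))
  # a 12 Hz burst shows up as a sigma-band peak in covering bins
  t <- (0:1999) / 1000
  x <- ifelse(t >= 0.7 & t < 1.3, sin(2 * pi * 12 * t), 0)
  spg <- spindle_spectrogram(x, 1000)
  bin <- which.min(abs(spg$times - 0.7))   # window [0.7, 1.3)
  pk <- spg$freqs[which.max(spg$power[bin, ])]
  expect_lt(abs(pk - 12), 1.7)
})

test_that("candidate criteria: recording-wide percentile and peak ratio", {
  freqs <- seq(0, 100, by = 5 / 3)
  n <- 200
  p <- matrix(0.1, n, length(freqs))
  isig <- which.min(abs(freqs - 12))
  ilow <- which.min(abs(freqs - 5))
  p[1:6, isig] <- 5                      # 3% of bins carry strong sigma peaks
  p[7, isig] <- 1; p[7, ilow] <- 2.5     # fails the 0.5x low-band ratio
  spg <- make_spectrogram(p, freqs, step_s = 0.1)
  cand <- detect_candidate_bins(spg)
  expect_true(all(cand$candidate[1:6]))
  expect_false(cand$candidate[7])        # 1 <= 0.5 * 2.5
  expect_equal(sum(cand$candidate), 6)
  # identical bins: none exceed their own percentile under strict >
  flat <- make_spectrogram(matrix(1, 50, length(freqs)), freqs, step_s = 0.1)
  expect_false(any(detect_candidate_bins(flat)$candidate))
})

test_that("event assembly: adjacency, gap fusion, duration and band majority", {
  params <- spindle_params()
  cand <- rep(FALSE, 40)
  cand[11:13] <- TRUE
  ev <- assemble_spindles(cand, params = params)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_bins, 3)
  expect_equal(ev$start_s, 1.0)
  # two runs separated by a 200 ms gap fuse (200 < 300)
  cand2 <- rep(FALSE, 40)
  cand2[c(5:7, 10:12)] <- TRUE
  ev2 <- assemble_spindles(cand2, params = params)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$n_bins, 8)
  # a 300 ms gap does not fuse
  cand3 <- rep(FALSE, 40)
  cand3[c(5:7, 11:13)] <- TRUE
  expect_equal(nrow(assemble_spindles(cand3, params = params)), 2)
  # an event spanning exactly 200 ms is discarded
  cand4 <- rep(FALSE, 40)
  cand4[5:6] <- TRUE
  expect_equal(nrow(assemble_spindles(cand4, params = params)), 0)
  # band-majority: 2 of 6 bins in band -> rejected
  cand5 <- rep(FALSE, 40)
  cand5[5:10] <- TRUE
  freqs5 <- c(rep(12, 2), rep(5, 4))
  pf <- rep(0, 40); pf[5:10] <- freqs5
  expect_equal(nrow(assemble_spindles(cand5, pf, params)), 0)
  pf[5:10] <- c(rep(12, 3), rep(5, 3))   # exactly half -> kept
  expect_equal(nrow(assemble_spindles(cand5, pf, params)), 1)
})

test_that("assembly equals brute-force merging and satisfies the universal bounds", {
  set.seed(13)
  params <- spindle_params()
  for (i in 1:300) {
    cand <- runif(sample(20:80, 1)) < 0.25
    ev <- assemble_spindles(cand, params = params)
    orc <- oracle_assemble(cand)
    expect_equal(nrow(ev), if (is.null(orc)) 0L else nrow(orc))
    if (!is.null(orc)) {
      expect_equal(ev$start_s, (orc[, 1] - 1L) * 0.1)
      expect_equal(ev$n_bins, orc[, 2] - orc[, 1] + 1L)
    }
    # universal assertions
    expect_true(all(ev$duration_ms > 200))
    if (nrow(ev) > 1) {
      gaps <- ev$start_s[-1] - ev$end_s[-nrow(ev)]
      expect_true(all(gaps >= 0.3 - 1e-9))
    }
  }
})

test_that("raising the percentile weakly decreases the candidate count", {
  set.seed(4)
  spg <- spindle_spectrogram(rnorm(20000), 1000)
  counts <- vapply(c(80, 90, 96, 99), function(q) {
    sum(detect_candidate_bins(spg, spindle_params(sigma_percentile = q))$candidate)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detector recovers injected bursts in pink noise", {
  sim <- simulate_spindle_eeg(duration_s = 300, fs = 1000, seed = 42)
  ev <- detect_spindles(sim$eeg, sim$fs)
  m <- match_events(ev, sim$truth, tol_s = 0.3)
  expect_gte(m$precision, 0.9)
  expect_gte(m$recall, 0.9)
  # NREM restriction clears candidates outside NREM epochs
  nep <- ceiling(300 / 2.5)
  allw <- new_hypnogram(rep("W", nep))
  expect_equal(nrow(detect_spindles(sim$eeg, sim$fs, hypnogram = allw)), 0)
})
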