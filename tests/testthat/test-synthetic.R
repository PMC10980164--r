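test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(duration_s = 900, fs_eeg = 200, seed = 123)
  a <- simulate_hypnogram(cfg)
  b <- simulate_hypnogram(cfg)
  expect_identical(as.character(a$hypnogram), as.character(b$hypnogram))
  expect_identical(a$ma_events, b$ma_events)
  sa <- synthesize_signals(a$hypnogram, cfg)
  sb <- synthesize_signals(b$hypnogram, cfg)
  expect_identical(sa$recording$eeg, sb$recording$eeg)
  expect_identical(sa$spindle_truth, sb$spindle_truth)
  pa <- synthesize_photometry(a$hypnogram, a$ma_events, cfg)
  pb <- synthesize_photometry(b$hypnogram, b$ma_events, cfg)
  expect_identical(pa$trace$sig465, pb$trace$sig465)
  expect_identical(schedule_tones(3600, seed = 9), schedule_tones(3600, seed = 9))
})

test_that("microarousal insertion respects rate, bounds and flanking", {
  cfg0 <- sim_config(duration_s = 3600, ma_rate_per_min_nrem = 0, seed = 2)
  sim0 <- simulate_hypnogram(cfg0)
  expect_equal(nrow(sim0$ma_events), 0)
  expect_equal(nrow(detect_microarousals(sim0$hypnogram)), 0)
  cfg <- sim_config(duration_s = 7200, seed = 3)
  sim <- simulate_hypnogram(cfg)
  expect_gt(nrow(sim$ma_events), 5)
  expect_true(all(sim$ma_events$duration_s <= 20))
  # every ground-truth MA is recovered by the detector on the labels
  ma <- detect_microarousals(sim$hypnogram)
  expect_equal(ma$start_s, sim$ma_events$start_s)
  expect_equal(ma$duration_s, sim$ma_events$duration_s)
})

test_that("state occupancy approaches the semi-Markov stationary fractions", {
  cfg <- sim_config(duration_s = 24 * 3600, ma_rate_per_min_nrem = 0, seed = 11)
  sim <- simulate_hypnogram(cfg)
  # embedded-chain visit rates: piW = piN * (1 - p_nr) + piR * p_rw,
  # piN = piW + piR * (1 - p_rw), piR = piN * p_nr; with piN = 1:
  piR <- cfg$p_n_to_r
  piW <- (1 - cfg$p_n_to_r) + piR * cfg$p_r_to_w
  occ <- c(W = piW * cfg$dwell_mean_s[["W"]], N = cfg$dwell_mean_s[["N"]],
           R = piR * cfg$dwell_mean_s[["R"]])
  occ <- occ / sum(occ) * 100
  got <- state_percentages(sim$hypnogram)
  expect_lt(max(abs(got - occ)), 5)
})

test_that("tone schedules have uniform gaps in the configured range", {
  on <- schedule_tones(4 * 3600, seed = 5)
  expect_true(all(diff(on) >= 240 & diff(on) <= 1200))
  expect_true(all(on + 20 < 4 * 3600))
  # boundary: a short recording gives zero or one onset
  expect_lte(length(schedule_tones(300, seed = 1)), 1)
})

test_that("spindle and transient ground truth follow their rate switches", {
  cfg <- sim_config(duration_s = 900, fs_eeg = 200, spindle_rate_per_min = 0,
                    seed = 4)
  sim <- simulate_hypnogram(cfg)
  expect_equal(nrow(synthesize_signals(sim$hypnogram, cfg)$spindle_truth), 0)
  cfgp <- sim_config(duration_s = 900, fs_eeg = 200, seed = 4,
                     p_transient_given_ma = 1,
                     transient_rate_per_min_nrem = 0)
  simp <- simulate_hypnogram(cfgp)
  ph <- synthesize_photometry(simp$hypnogram, simp$ma_events, cfgp)
  # transients sit exactly at MA onsets (minus any merged within 10 s)
  expect_true(all(ph$transient_truth$time_s %in% simp$ma_events$start_s))
})

test_that("sigma-power modulation is present only when depth > 0", {
  base <- list(duration_s = 2400, fs_eeg = 200, seed = 6,
               dwell_mean_s = c(W = 60, N = 2000, R = 60),
               ma_rate_per_min_nrem = 0)
  for (depth in c(0, 0.8)) {
    cfg <- do.call(sim_config, c(base, list(infraslow_depth = depth)))
    sim <- simulate_hypnogram(cfg)
    rec <- synthesize_signals(sim$hypnogram, cfg)$recording
    spg <- compute_spectrogram(rec$eeg, rec$fs)
    stc <- sigma_timecourse(normalize_spectrogram(spg))
    bouts <- consolidate_nrem(sim$hypnogram)
    psd <- infraslow_psd(stc, bouts)
    peak_band <- sleeprhythms:::.trapz_band(psd$freqs, psd$density,
                                            0.015, 0.025)
    ref_band <- sleeprhythms:::.trapz_band(psd$freqs, psd$density, 0.08, 0.12)
    if (depth == 0) {
      expect_lt(peak_band / (ref_band + 1e-12), 5)   # no dominant 0.02 Hz peak
    } else {
      expect_gt(peak_band / (ref_band + 1e-12), 8)   # clear modulation peak
    }
  }
})
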