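test_that("trial eligibility and outcomes on hand-worked micro-hypnograms", {
  # 200 s of NREM, tone at 150 s, wake 5 s after onset -> arousal
  h <- new_hypnogram(c(rep("N", 62), rep("W", 4), rep("N", 30)))
  tr <- classify_tone_trials(h, 150)
  expect_true(tr$eligible)
  expect_equal(tr$outcome, "arousal")
  # NREM throughout the 20 s tone -> sleep-through
  h2 <- new_hypnogram(rep("N", 96))
  tr2 <- classify_tone_trials(h2, 150)
  expect_equal(tr2$outcome, "sleep_through")
  # onset during wake -> ineligible
  h3 <- new_hypnogram(c(rep("W", 62), rep("N", 34)))
  expect_equal(classify_tone_trials(h3, 150)$outcome, "ineligible")
  # only 60 s of NREM before onset (< 120 s) -> ineligible
  h4 <- new_hypnogram(c(rep("W", 38), rep("N", 58)))
  tr4 <- classify_tone_trials(h4, 155)
  expect_false(tr4$eligible)
  expect_equal(tr4$nrem_before_s, 60)
  # exactly 120 s is not enough (strict >)
  tr5 <- classify_tone_trials(h4, 215)
  expect_false(tr5$eligible)
  tr6 <- classify_tone_trials(h4, 217.5)
  expect_true(tr6$eligible)
  # MA-bridged NREM counts toward eligibility
  h7 <- new_hypnogram(c(rep("N", 40), rep("W", 4), rep("N", 52)))
  tr7 <- classify_tone_trials(h7, 200)
  expect_true(tr7$eligible)
  expect_equal(tr7$nrem_before_s, 200)
  # onset beyond the hypnogram -> ineligible with NA context
  tr8 <- classify_tone_trials(h7, 1e5)
  expect_equal(tr8$outcome, "ineligible")
  # episode mode measures the whole bridged span instead
  tr9 <- classify_tone_trials(h7, 10, eligibility = "episode")
  expect_true(tr9$eligible)
})

test_that("every eligible trial is exactly one of arousal / sleep-through", {
  set.seed(19)
  for (i in 1:20) {
    h <- random_hypnogram(400, prob = c(W = 0.2, N = 0.7, R = 0.1))
    tones <- sort(runif(8, 0, 1000))
    tr <- classify_tone_trials(h, tones)
    expect_true(all(tr$outcome[tr$eligible] %in% c("arousal", "sleep_through")))
    expect_true(all(tr$outcome[!tr$eligible] == "ineligible"))
  }
})

test_that("pre-tone sigma traces average per class", {
  stc <- structure(list(times = (0:399) * 2.5,
                        values = sin(2 * pi * 0.02 * (0:399) * 2.5) + 2,
                        step_s = 2.5),
                   class = "sigma_timecourse")
  trials <- data.frame(onset_s = c(300, 600), eligible = TRUE,
                       outcome = "arousal")
  expect_warning(peri <- peri_tone_sigma(stc, trials), "sleep_through")
  expect_equal(length(peri$arousal$mean), 24)        # 60 s at 2.5 s bins
  expect_true(all(peri$arousal$n == 2))
  # identical trial traces -> the mean equals the common trace
  trials2 <- data.frame(onset_s = c(300, 300), eligible = TRUE,
                        outcome = "arousal")
  suppressWarnings(peri2 <- peri_tone_sigma(stc, trials2))
  idx <- round((300 + peri2$arousal$lag_s) / 2.5) + 1
  expect_equal(peri2$arousal$mean, stc$values[idx])
  # slope helper: a descending ramp has a negative slope
  ramp <- list(lag_s = seq(-60, -2.5, by = 2.5),
               mean = seq(2, 1, length.out = 24))
  expect_lt(pre_tone_slope(ramp), 0)
})

test_that("phase-coupled arousals leave the descending/ascending sigma signature", {
  cfg <- sim_config(duration_s = 7200, fs_eeg = 200, seed = 5,
                    dwell_mean_s = c(W = 90, N = 600, R = 60),
                    ma_rate_per_min_nrem = 0.3, infraslow_depth = 0.9)
  ses <- simulate_arousal_session(cfg, coupling = "phase",
                                  min_gap_s = 240, max_gap_s = 420)
  spg <- compute_spectrogram(ses$recording$eeg, ses$recording$fs)
  stc <- sigma_timecourse(normalize_spectrogram(spg))
  trials <- classify_tone_trials(ses$hypnogram, ses$tone_onsets)
  expect_gt(sum(trials$eligible), 5)
  peri <- peri_tone_sigma(stc, trials)
  expect_lt(pre_tone_slope(peri$arousal), 0)
  expect_gt(pre_tone_slope(peri$sleep_through), 0)
})
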