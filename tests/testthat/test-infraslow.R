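# helper: a normalized spectrogram whose sigma rows carry a known modulation
modulated_spectrogram <- function(n_epochs, f_mod, depth = 1, step_s = 2.5) {
  freqs <- seq(0, 20, by = 0.5)
  t <- (seq_len(n_epochs) - 1) * step_s
  p <- matrix(1, nrow = n_epochs, ncol = length(freqs))
  mod <- 1 + depth * sin(2 * pi * f_mod * t)
  inband <- freqs >= 10.5 & freqs <= 16
  p[, inband] <- matrix(mod, n_epochs, sum(inband))
  # renormalise rows so temporal means are exactly 1
  p <- sweep(p, 2, colMeans(p), `/`)
  spg <- make_spectrogram(p, freqs, step_s)
  spg$normalized <- TRUE
  spg
}

test_that("sigma time course averages the normalized band and rejects raw input", {
  spg <- modulated_spectrogram(240, 0.02)
  stc <- sigma_timecourse(spg)
  t <- (0:239) * 2.5
  mod <- 1 + sin(2 * pi * 0.02 * t)
  expect_equal(stc$values, mod / mean(mod), tolerance = 1e-12)
  # constant normalized spectrogram -> constant 1
  spg2 <- modulated_spectrogram(50, 0.02, depth = 0)
  expect_equal(sigma_timecourse(spg2)$values, rep(1, 50))
  # unnormalized input refused
  raw <- make_spectrogram(matrix(rexp(500), 50), seq(0, 4.5, 0.5))
  expect_error(sigma_timecourse(raw), "not normalized")
})

test_that("per-bout PSD peaks at the modulation frequency", {
  spg <- modulated_spectrogram(240, 0.02)   # one 600 s block
  stc <- sigma_timecourse(spg)
  bouts <- data.frame(start_s = 0, end_s = 600, span_s = 600,
                      start_epoch = 1, end_epoch = 240, n_ma = 0)
  psd <- infraslow_psd(stc, bouts)
  expect_equal(psd$n_bouts, 1)
  grid_step <- psd$freqs[2] - psd$freqs[1]
  expect_lte(abs(psd$peak_freq_hz - 0.02), grid_step)
  # constant series -> essentially no power anywhere above DC
  stc0 <- sigma_timecourse(modulated_spectrogram(240, 0.02, depth = 0))
  psd0 <- infraslow_psd(stc0, bouts)
  expect_lt(max(psd0$density[-1]), 1e-20)
  # no qualifying bout -> error
  short <- data.frame(start_s = 0, end_s = 100, span_s = 100,
                      start_epoch = 1, end_epoch = 40, n_ma = 0)
  expect_error(infraslow_psd(stc, short), "120 s")
})

test_that("white-noise sigma series yields a flat PSD on average", {
  set.seed(5)
  freqs <- seq(0, 20, by = 0.5)
  dens <- replicate(40, {
    p <- matrix(rexp(200 * length(freqs)), 200)
    p <- sweep(p, 2, colMeans(p), `/`)
    spg <- make_spectrogram(p, freqs)
    spg$normalized <- TRUE
    stc <- sigma_timecourse(spg)
    bouts <- data.frame(start_s = 0, end_s = 500, span_s = 500,
                        start_epoch = 1, end_epoch = 200, n_ma = 0)
    infraslow_psd(stc, bouts)$density
  })
  m <- rowMeans(dens)
  inner <- m[3:(length(m) - 2)]
  expect_lt(max(inner) / min(inner), 3.5)   # no systematic spectral shape
})

test_that("strength is the area difference of the stated bands and is linear", {
  freqs <- seq(0, 0.2, by = 0.005)
  flat <- list(freqs = freqs, density = rep(3, length(freqs)))
  # equal density d: strength = d*0.03 - d*0.04 = -0.01 d
  expect_equal(infraslow_strength(flat), -0.03, tolerance = 1e-12)
  lowonly <- list(freqs = freqs,
                  density = ifelse(freqs >= 0.01 & freqs <= 0.04, 2, 0))
  expect_gt(infraslow_strength(lowonly), 0)
  highonly <- list(freqs = freqs,
                   density = ifelse(freqs >= 0.08 & freqs <= 0.12, 2, 0))
  expect_lt(infraslow_strength(highonly), 0)
  # linearity: strength(aP + bQ) = a strength(P) + b strength(Q)
  set.seed(8)
  P <- list(freqs = freqs, density = rexp(length(freqs)))
  Q <- list(freqs = freqs, density = rexp(length(freqs)))
  aPbQ <- list(freqs = freqs, density = 2 * P$density + 5 * Q$density)
  expect_equal(infraslow_strength(aPbQ),
               2 * infraslow_strength(P) + 5 * infraslow_strength(Q),
               tolerance = 1e-12)
  expect_error(infraslow_strength(list(freqs = seq(0, 0.05, 0.005),
                                       density = rep(1, 11))), "cover")
})

test_that("peak frequency search window and tie behaviour", {
  freqs <- seq(0, 0.2, by = 0.005)
  dec <- list(freqs = freqs, density = rev(seq_along(freqs)))
  expect_equal(infraslow_peak_frequency(dec), 0.005)  # monotone decreasing
  expect_error(infraslow_peak_frequency(dec, search = c(0.3, 0.4)), "search")
  # tie resolves to the lowest frequency
  tied <- list(freqs = freqs, density = rep(1, length(freqs)))
  expect_equal(infraslow_peak_frequency(tied), 0.005)
})
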