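# Synthetic-data generator: ground-truth-labelled recordings with the
# statistical structure the analysis stages assume — state-dependent EEG
# spectra, EMG tone by state, infraslow amplitude modulation of the sigma
# band during NREM, spindle bursts, microarousals, photometry transients
# coupled to microarousals, and randomized tone schedules.  Everything is
# deterministic under the configured seed.

#' Simulation configuration
#'
#' Defaults describe a realistic mouse sleep recording: exponential dwell
#' times (wake 180 s, NREM 240 s, REM 75 s; REM entered only from NREM),
#' microarousals at 0.8 per minute of NREM lasting 2.5-12.5 s, an infraslow
#' sigma-amplitude modulation at 0.02 Hz with depth 0.6, spindles at 5 per
#' NREM minute (500-800 ms, 12 Hz), calcium transients at 1 per NREM minute
#' plus a 0.9 probability of a transient at each MA onset (microarousals are typically accompanied by noradrenergic transients), and a shared
#' photobleaching time constant of 3000 s.  State band amplitudes (µV) give
#' a delta-dominant NREM, theta-dominant REM and broadband/gamma wake with
#' EMG RMS wake >> NREM >= REM.
#'
#' @param duration_s recording length (s).
#' @param fs_eeg EEG/EMG sampling rate (Hz).
#' @param fs_photo photometry sampling rate (Hz).
#' @param seed integer seed fixing all randomness.
#' @param dwell_mean_s named exponential dwell means per state (s).
#' @param p_n_to_r probability that a NREM bout ends in REM (else wake).
#' @param p_r_to_w probability that a REM bout ends in wake (else NREM).
#' @param ma_rate_per_min_nrem microarousal rate (per NREM minute).
#' @param ma_dur_range_s MA duration range (s), within (0, 20].
#' @param band_amp_uv per-state component amplitudes (µV): named list with
#'   vectors `c(delta, theta, sigma, gamma, broad)` for `W`, `N`, `R`.
#' @param emg_rms_uv per-state EMG RMS (µV).
#' @param infraslow_freq_hz,infraslow_depth sigma-modulation frequency and
#'   depth (0-1).
#' @param spindle_rate_per_min spindle rate per NREM minute.
#' @param spindle_dur_ms spindle duration range (ms).
#' @param spindle_freq_hz spindle oscillation frequency.
#' @param spindle_amp_uv spindle burst amplitude (µV).
#' @param transient_rate_per_min_nrem rate of MA-independent calcium
#'   transients per NREM minute.
#' @param p_transient_given_ma probability of a transient at each MA onset.
#' @param transient_amp,transient_width_s transient kernel amplitude (dF/F
#'   units) and full width (s).
#' @param bleach_tau_s photobleaching time constant (s).
#' @param photo_noise_sd sensor noise SD on the raw fluorescence.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 7200, fs_eeg = 1000, fs_photo = 100,
                       seed = 1L,
                       dwell_mean_s = c(W = 180, N = 240, R = 75),
                       p_n_to_r = 0.35, p_r_to_w = 0.8,
                       ma_rate_per_min_nrem = 0.8,
                       ma_dur_range_s = c(2.5, 12.5),
                       band_amp_uv = list(
                         W = c(delta = 15, theta = 18, sigma = 8,
                               gamma = 20, broad = 15),
                         N = c(delta = 45, theta = 15, sigma = 18,
                               gamma = 4, broad = 8),
                         R = c(delta = 10, theta = 40, sigma = 8,
                               gamma = 5, broad = 8)),
                       emg_rms_uv = c(W = 60, N = 8, R = 5),
                       infraslow_freq_hz = 0.02, infraslow_depth = 0.6,
                       spindle_rate_per_min = 5,
                       spindle_dur_ms = c(500, 800),
                       spindle_freq_hz = 12, spindle_amp_uv = 50,
                       transient_rate_per_min_nrem = 1,
                       p_transient_given_ma = 0.9,
                       transient_amp = 0.08, transient_width_s = 10,
                       bleach_tau_s = 3000, photo_noise_sd = 0.003) {
  stopifnot(duration_s > 0, fs_eeg > 0, fs_photo > 0,
            infraslow_depth >= 0, infraslow_depth <= 1,
            ma_rate_per_min_nrem >= 0, spindle_rate_per_min >= 0,
            transient_rate_per_min_nrem >= 0,
            p_transient_given_ma >= 0, p_transient_given_ma <= 1,
            ma_dur_range_s[1] > 0, ma_dur_range_s[2] <= 20)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a ground-truth hypnogram with microarousals
#'
#' Semi-Markov state sequence over Wake/NREM/REM (REM entered only from
#' NREM) with exponential dwell times quantized to 2.5 s epochs, then wake
#' interruptions of at most 20 s (microarousals) inserted into NREM runs at
#' the configured rate.
#'
#' @param config a [sim_config()].
#' @return list with `hypnogram` (a `hypnogram`), `ma_events` (data.frame
#'   `start_s`, `duration_s`) and `config`.
#' @export
simulate_hypnogram <- function(config) {
  set.seed(config$seed)
  ep <- 2.5
  n_epochs <- floor(config$duration_s / ep)
  if (n_epochs < 1) stop("duration too short for one epoch")
  states <- character(0)
  cur <- "W"
  while (length(states) < n_epochs) {
    dwell <- stats::rexp(1, 1 / config$dwell_mean_s[[cur]])
    # natural wake bouts stay above the 20 s microarousal bound: brief
    # wake intrusions come only from the explicit MA process below
    kmin <- if (cur == "W") 9L else 1L
    k <- max(kmin, round(dwell / ep))
    states <- c(states, rep(cur, k))
    cur <- switch(cur,
                  W = "N",
                  N = if (stats::runif(1) < config$p_n_to_r) "R" else "W",
                  R = if (stats::runif(1) < config$p_r_to_w) "W" else "N")
  }
  states <- states[seq_len(n_epochs)]

  # insert MAs into maximal N runs
  r <- rle(states)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  ma <- list()
  d_lo <- max(1L, round(config$ma_dur_range_s[1] / ep))
  d_hi <- max(d_lo, round(config$ma_dur_range_s[2] / ep))
  for (i in which(r$values == "N")) {
    L <- r$lengths[i]
    k <- stats::rpois(1, config$ma_rate_per_min_nrem * L * ep / 60)
    if (k == 0 || L < 4) next
    taken <- rep(FALSE, L)
    for (j in seq_len(k)) {
      d <- sample(d_lo:d_hi, 1)
      if (L - d < 3) next
      pos <- sample(2:(L - d), 1)      # keep >= 1 N epoch on each side
      span <- max(1, pos - 1):min(L, pos + d)
      if (any(taken[span])) next       # keep MAs separated by >= 1 N epoch
      taken[span] <- TRUE
      idx <- run_start[i] + pos - 1L
      states[idx:(idx + d - 1L)] <- "W"
      ma[[length(ma) + 1L]] <- data.frame(start_s = (idx - 1L) * ep,
                                          duration_s = d * ep)
    }
  }
  ma <- if (length(ma)) do.call(rbind, ma) else
    data.frame(start_s = numeric(), duration_s = numeric())
  ma <- ma[order(ma$start_s), , drop = FALSE]
  rownames(ma) <- NULL
  list(hypnogram = new_hypnogram(states, epoch_s = ep), ma_events = ma,
       config = config)
}

#' Synthesize EEG and EMG signals for a hypnogram
#'
#' The EEG is a sum of band-limited Gaussian noise components (delta 0.5-4,
#' theta 5-12, sigma 10.5-16, gamma 100-150 Hz where the sampling rate
#' allows, plus a 0.5-100 Hz broadband floor) whose amplitudes switch with
#' the state; during NREM the sigma component's amplitude is modulated as
#' `sqrt(1 + depth * sin(2 pi f t))` so the sigma POWER oscillates at the
#' infraslow frequency with the configured depth.  Spindle bursts
#' (Tukey-enveloped sinusoids) are injected during NREM at the configured
#' rate and reported as ground truth.  The EMG is 50-500 Hz band noise with
#' state-dependent RMS.
#'
#' @param hypnogram a `hypnogram` (e.g. from [simulate_hypnogram()]).
#' @param config a [sim_config()].
#' @return list with `recording` (a [new_recording()]) and
#'   `spindle_truth` (data.frame `start_s`, `end_s`).
#' @export
synthesize_signals <- function(hypnogram, config) {
  set.seed(config$seed + 1L)
  fs <- config$fs_eeg
  ep <- attr(hypnogram, "epoch_s") %||% 2.5
  st <- as.character(hypnogram)
  n <- round(length(st) * ep * fs)
  samp_state <- rep(st, each = round(ep * fs))[seq_len(n)]
  t <- (seq_len(n) - 1) / fs
  nyq <- fs / 2
  amp_of <- function(comp) {
    vapply(c("W", "N", "R"), function(s) config$band_amp_uv[[s]][[comp]],
           numeric(1))[match(samp_state, c("W", "N", "R"))]
  }
  eeg <- amp_of("delta") * band_limited_noise(n, fs, 0.5, min(4, nyq * 0.9)) +
    amp_of("theta") * band_limited_noise(n, fs, 5, min(12, nyq * 0.9)) +
    amp_of("broad") * band_limited_noise(n, fs, 0.5, min(100, nyq * 0.95))
  sig_env <- amp_of("sigma")
  is_n <- samp_state == "N"
  sig_env[is_n] <- sig_env[is_n] *
    sqrt(1 + config$infraslow_depth *
           sin(2 * pi * config$infraslow_freq_hz * t[is_n]))
  eeg <- eeg + sig_env * band_limited_noise(n, fs, 10.5, min(16, nyq * 0.9))
  if (nyq > 110) {
    eeg <- eeg + amp_of("gamma") * band_limited_noise(n, fs, 100, min(150, nyq * 0.95))
  }

  # spindle bursts during NREM
  truth <- list()
  r <- rle(st)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  for (i in which(r$values == "N")) {
    run_dur <- r$lengths[i] * ep
    k <- stats::rpois(1, config$spindle_rate_per_min * run_dur / 60)
    if (k == 0) next
    t0_run <- (run_start[i] - 1L) * ep
    for (j in seq_len(k)) {
      dur <- stats::runif(1, config$spindle_dur_ms[1],
                          config$spindle_dur_ms[2]) / 1000
      s0 <- t0_run + stats::runif(1, 0, max(0.001, run_dur - dur))
      i0 <- floor(s0 * fs) + 1L
      m <- round(dur * fs)
      if (i0 + m - 1L > n) next
      env <- tukey_window(m)
      tt <- (seq_len(m) - 1) / fs
      eeg[i0:(i0 + m - 1L)] <- eeg[i0:(i0 + m - 1L)] +
        config$spindle_amp_uv * env *
        sin(2 * pi * config$spindle_freq_hz * tt)
      truth[[length(truth) + 1L]] <- data.frame(start_s = s0,
                                                end_s = s0 + dur)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(start_s = numeric(), end_s = numeric())
  truth <- truth[order(truth$start_s), , drop = FALSE]
  rownames(truth) <- NULL

  emg_rms <- config$emg_rms_uv[match(samp_state, c("W", "N", "R"))]
  emg <- emg_rms * band_limited_noise(n, fs, 50, min(500, nyq * 0.999))
  list(recording = new_recording(eeg, emg, fs), spindle_truth = truth)
}

#' Synthesize a spindle-detection benchmark EEG
#'
#' Pink-noise (1/f) background with Tukey-enveloped sinusoidal bursts at
#' known times; the burst amplitude is `amp_rel` times the background's RMS
#' inside the spindle sigma band.
#'
#' @param duration_s signal length (s).
#' @param fs sampling rate (Hz).
#' @param rate_per_min burst rate (per minute).
#' @param dur_ms burst duration range (ms).
#' @param freq_hz burst frequency (Hz).
#' @param amp_rel burst amplitude relative to the background sigma-band RMS.
#' @param min_gap_s minimum gap between consecutive bursts (s).
#' @param seed RNG seed.
#' @return list with `eeg`, `fs`, `truth` (data.frame `start_s`, `end_s`).
#' @export
simulate_spindle_eeg <- function(duration_s = 600, fs = 1000,
                                 rate_per_min = 5, dur_ms = c(500, 800),
                                 freq_hz = 12, amp_rel = 5, min_gap_s = 2,
                                 seed = 1L) {
  set.seed(seed)
  n <- round(duration_s * fs)
  bg <- 20 * pink_noise(n, fs)
  # background RMS inside the sigma band
  spec <- stats::fft(bg)
  f <- abs(seq(0, fs, length.out = n + 1)[1:n]); f <- pmin(f, fs - f)
  band <- Re(stats::fft(ifelse(f >= 10 & f <= 16.67, 1, 0) * spec,
                        inverse = TRUE)) / n
  amp <- amp_rel * sqrt(mean(band^2))
  k <- stats::rpois(1, rate_per_min * duration_s / 60)
  starts <- sort(stats::runif(k, 1, duration_s - 2))
  keep <- c(TRUE, diff(starts) > min_gap_s)
  starts <- starts[keep]
  eeg <- bg
  truth <- data.frame(start_s = numeric(), end_s = numeric())
  for (s0 in starts) {
    dur <- stats::runif(1, dur_ms[1], dur_ms[2]) / 1000
    i0 <- floor(s0 * fs) + 1L
    m <- round(dur * fs)
    if (i0 + m - 1L > n) next
    env <- tukey_window(m)
    tt <- (seq_len(m) - 1) / fs
    eeg[i0:(i0 + m - 1L)] <- eeg[i0:(i0 + m - 1L)] +
      amp * env * sin(2 * pi * freq_hz * tt)
    truth <- rbind(truth, data.frame(start_s = s0, end_s = s0 + dur))
  }
  list(eeg = eeg, fs = fs, truth = truth)
}

#' Synthesize dual-wavelength photometry with ground-truth transients
#'
#' The 465 nm channel is `F0 * exp(-t/tau) * (1 + state offset + transient
#' kernels + shared motion) + noise` with state offsets wake > NREM > REM
#' (REM near silent); transients are smooth ~10 s bumps placed at MA onsets
#' with probability `p_transient_given_ma` plus MA-independent NREM
#' transients at the configured rate.  The 405 nm reference shares the
#' bleaching and motion but carries no transients or state modulation.
#'
#' @param hypnogram a `hypnogram`.
#' @param ma_events data.frame with `start_s`, `duration_s`.
#' @param config a [sim_config()].
#' @return list with `trace` (a [photometry_trace()]) and
#'   `transient_truth` (data.frame `time_s` of kernel centers).
#' @export
synthesize_photometry <- function(hypnogram, ma_events, config) {
  set.seed(config$seed + 2L)
  fs <- config$fs_photo
  ep <- attr(hypnogram, "epoch_s") %||% 2.5
  st <- as.character(hypnogram)
  n <- round(length(st) * ep * fs)
  t <- (seq_len(n) - 1) / fs
  samp_state <- rep(st, each = round(ep * fs))[seq_len(n)]
  offset <- c(W = 0.08, N = 0.03, R = 0.0)[match(samp_state, c("W", "N", "R"))]

  times <- numeric(0)
  if (nrow(ma_events)) {
    hit <- stats::runif(nrow(ma_events)) < config$p_transient_given_ma
    times <- ma_events$start_s[hit]
  }
  r <- rle(st)
  run_end <- cumsum(r$lengths); run_start <- run_end - r$lengths + 1L
  for (i in which(r$values == "N")) {
    run_dur <- r$lengths[i] * ep
    k <- stats::rpois(1, config$transient_rate_per_min_nrem * run_dur / 60)
    if (k) {
      times <- c(times, (run_start[i] - 1L) * ep +
                   stats::runif(k, 0, run_dur))
    }
  }
  times <- sort(times)
  # drop transients closer than the kernel width (they would merge)
  if (length(times) > 1) {
    times <- times[c(TRUE, diff(times) > config$transient_width_s)]
  }
  sdk <- config$transient_width_s / 2.355   # width read as FWHM
  transients <- rep(0, n)
  for (tc in times) {
    sel <- which(abs(t - tc) < 4 * sdk)
    transients[sel] <- transients[sel] +
      config$transient_amp * exp(-(t[sel] - tc)^2 / (2 * sdk^2))
  }
  motion <- 0.005 * sosfiltfilt(butter_lowpass_sos(4, 0.5, fs),
                                stats::rnorm(n)) * sqrt(fs)
  bleach <- exp(-t / config$bleach_tau_s)
  s465 <- 2.0 * bleach * (1 + offset + transients + motion) +
    config$photo_noise_sd * stats::rnorm(n)
  s405 <- 1.5 * bleach * (1 + motion) +
    config$photo_noise_sd * stats::rnorm(n)
  list(trace = photometry_trace(s465, s405, fs),
       transient_truth = data.frame(time_s = times))
}

#' Random tone schedule
#'
#' Tone onsets with i.i.d. uniform gaps in `[min_gap_s, max_gap_s]`
#' (acoustic stimuli presented randomly every 4-20 minutes), truncated so
#' every tone fits inside the recording.
#'
#' @param duration_s recording length (s).
#' @param min_gap_s,max_gap_s gap range (s).
#' @param tone_dur_s tone duration (s); the last onset leaves room for it.
#' @param seed RNG seed.
#' @return numeric vector of onset times (possibly empty).
#' @export
schedule_tones <- function(duration_s, min_gap_s = 240, max_gap_s = 1200,
                           tone_dur_s = 20, seed = 1L) {
  stopifnot(duration_s > min_gap_s)
  set.seed(seed)
  onsets <- numeric(0)
  t <- stats::runif(1, min_gap_s, max_gap_s)
  while (t + tone_dur_s < duration_s) {
    onsets <- c(onsets, t)
    t <- t + stats::runif(1, min_gap_s, max_gap_s)
  }
  onsets
}

#' Simulate a sound-presentation session
#'
#' Builds a long-NREM hypnogram, schedules tones, and imposes tone outcomes:
#' with `coupling = "phase"` the animal wakes when the infraslow sigma
#' modulation is on its descending phase at tone onset (wake probability
#' `p_descend` there, `p_ascend` otherwise) — the phase-tuning signature of
#' sound-evoked arousals; with `coupling = "independent"` every eligible
#' tone wakes the animal with probability `p_arousal` regardless of phase.
#' Arousals are realized by overwriting ~10 s of epochs with wake shortly
#' after the onset.
#'
#' @param config a [sim_config()]; dwell means with long NREM bouts are
#'   recommended (see examples in the package tests).
#' @param coupling `"phase"` or `"independent"`.
#' @param p_arousal wake probability in independent mode.
#' @param p_descend,p_ascend wake probabilities on the descending /
#'   ascending infraslow phase in phase mode.
#' @param min_gap_s,max_gap_s tone schedule gaps (s).
#' @param synthesize when `FALSE`, skip signal synthesis (`recording` is
#'   `NULL`); hypnogram-level analyses need only the labels.
#' @return list with `hypnogram`, `recording`, `tone_onsets`,
#'   `truth` (data.frame `onset_s`, `woke`, `descending`), `ma_events`.
#' @export
simulate_arousal_session <- function(config,
                                     coupling = c("phase", "independent"),
                                     p_arousal = 0.5,
                                     p_descend = 0.95, p_ascend = 0.05,
                                     min_gap_s = 240, max_gap_s = 480,
                                     synthesize = TRUE) {
  coupling <- match.arg(coupling)
  sim <- simulate_hypnogram(config)
  onsets <- schedule_tones(config$duration_s, min_gap_s, max_gap_s,
                           seed = config$seed + 3L)
  set.seed(config$seed + 4L)
  st <- as.character(sim$hypnogram)
  ep <- attr(sim$hypnogram, "epoch_s")
  truth <- data.frame(onset_s = onsets, woke = FALSE, descending = NA)
  for (i in seq_along(onsets)) {
    onset <- onsets[i]
    epo <- floor(onset / ep) + 1L
    if (epo > length(st) || st[epo] != "N") next
    descending <- cos(2 * pi * config$infraslow_freq_hz * onset) < 0
    p <- if (coupling == "phase") {
      if (descending) p_descend else p_ascend
    } else p_arousal
    truth$descending[i] <- descending
    if (stats::runif(1) < p) {
      truth$woke[i] <- TRUE
      w0 <- epo + 2L                       # wake ~5 s after tone onset
      w1 <- min(length(st), w0 + 3L)       # ~10 s of wake
      st[w0:w1] <- "W"
    }
  }
  hyp <- new_hypnogram(st, epoch_s = ep)
  rec <- if (synthesize) synthesize_signals(hyp, config)$recording else NULL
  list(hypnogram = hyp, recording = rec, tone_onsets = onsets,
       truth = truth, ma_events = sim$ma_events)
}
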