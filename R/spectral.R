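# Epoch-resolution Welch spectrograms and band powers.  These feed every
# downstream stage: staging thresholds, the infraslow sigma-power analysis,
# and state-resolved summaries.

#' EEG/EMG spectrogram with 2.5 s epoch resolution
#'
#' Power spectral density estimated for sliding, half-overlapping windows of
#' `window_s` seconds (default 5 s, giving one column every 2.5 s).  Within
#' each window the PSD is computed by Welch's method: half-overlapping
#' subwindows of `subwindow_s` seconds (default 2 s), each mean-detrended,
#' Hann-tapered, and averaged, for a frequency resolution of
#' `1/subwindow_s` = 0.5 Hz.  Column time stamps mark the window START, so
#' epoch `i` summarises the half-open interval `[2.5*(i-1), 2.5*(i-1)+5)` s.
#'
#' @param signal numeric vector (µV).
#' @param fs sampling rate (Hz).
#' @param window_s outer window length in seconds.
#' @param overlap outer window overlap fraction.
#' @param subwindow_s Welch subwindow length in seconds.
#' @param subwindow_overlap Welch subwindow overlap fraction.
#' @return an object of class `sleep_spectrogram`: list with `times` (s,
#'   window starts), `freqs` (Hz), `power` (time x frequency matrix,
#'   µV²/Hz), and the window parameters.
#' @export
#' @examples
#' spg <- compute_spectrogram(sin(2 * pi * 2 * seq(0, 60, by = 1e-3)), fs = 1000)
#' dim(spg$power)
compute_spectrogram <- function(signal, fs, window_s = 5, overlap = 0.5,
                                subwindow_s = 2, subwindow_overlap = 0.5) {
  stopifnot(fs > 0, window_s > 0, subwindow_s <= window_s)
  nbad <- which(is.na(signal))
  if (length(nbad)) {
    stop("signal contains NaN/NA; first at index ", nbad[1])
  }
  nwin <- round(window_s * fs)
  if (length(signal) < nwin) {
    stop("signal shorter than one analysis window (", window_s, " s)")
  }
  step_s <- window_s * (1 - overlap)
  nstep <- round(step_s * fs)
  nsub <- round(subwindow_s * fs)
  nsubstep <- round(subwindow_s * (1 - subwindow_overlap) * fs)
  n_sub_per_win <- (nwin - nsub) %/% nsubstep + 1L
  n_times <- (length(signal) - nwin) %/% nstep + 1L

  # gather every subwindow of every outer window into one matrix, FFT once
  win_starts <- (seq_len(n_times) - 1L) * nstep
  sub_off <- (seq_len(n_sub_per_win) - 1L) * nsubstep
  starts <- rep(win_starts, each = n_sub_per_win) +
    rep(sub_off, times = n_times)
  idx <- outer(seq_len(nsub), starts, `+`)
  segs <- matrix(signal[idx], nrow = nsub)
  segs <- sweep(segs, 2, colMeans(segs))          # constant detrend
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nsub) - 1) / nsub))  # periodic Hann
  segs <- segs * w
  X <- stats::mvfft(segs)
  nfreq <- nsub %/% 2 + 1L
  P <- (Mod(X[seq_len(nfreq), , drop = FALSE])^2) / (fs * sum(w^2))
  if (nfreq > 2) P[2:(nfreq - 1L), ] <- 2 * P[2:(nfreq - 1L), ]
  # average subwindow periodograms within each outer window
  grp <- rep(seq_len(n_times), each = n_sub_per_win)
  power <- t(rowsum(t(P), grp) / n_sub_per_win)
  structure(list(times = win_starts / fs,
                 freqs = seq(0, fs / 2, by = 1 / subwindow_s),
                 power = t(power),
                 fs = fs, window_s = window_s, step_s = step_s),
            class = "sleep_spectrogram")
}

#' @export
print.sleep_spectrogram <- function(x, ...) {
  cat("<sleep_spectrogram> ", nrow(x$power), " epochs x ",
      ncol(x$power), " frequencies (0-", max(x$freqs), " Hz, step ",
      x$freqs[2] - x$freqs[1], " Hz), epoch step ", x$step_s, " s\n", sep = "")
  invisible(x)
}

#' Integrated band power per epoch
#'
#' Sums spectral density over all frequency bins inside the closed interval
#' `[lo, hi]` and multiplies by the bin width.  Both edge bins are included
#' (band limits are stated inclusively), so on the 0.5 Hz grid a band
#' `[0.5, 4]` integrates 8 bins.
#'
#' @param spectrogram a `sleep_spectrogram`.
#' @param band numeric length-2, band edges in Hz.
#' @return numeric vector, one value (µV²) per epoch.
#' @export
band_power <- function(spectrogram, band) {
  stopifnot(inherits(spectrogram, "sleep_spectrogram"),
            length(band) == 2, band[1] < band[2])
  f <- spectrogram$freqs
  if (band[1] < min(f) - 1e-9 || band[2] > max(f) + 1e-9) {
    stop("band [", band[1], ", ", band[2], "] Hz outside the frequency grid [",
         min(f), ", ", max(f), "] Hz")
  }
  sel <- f >= band[1] - 1e-9 & f <= band[2] + 1e-9
  df <- f[2] - f[1]
  as.numeric(spectrogram$power[, sel, drop = FALSE] %*% rep(df, sum(sel)))
}

#' Normalize a spectrogram by each frequency's temporal mean
#'
#' Divides every frequency row by its own mean over time, yielding a
#' dimensionless spectrogram in which each frequency has temporal mean 1.
#' This is the normalisation underlying the infraslow sigma-power analysis.
#'
#' @param spectrogram a `sleep_spectrogram`.
#' @return a `sleep_spectrogram` with dimensionless power and attribute
#'   `normalized = TRUE`.
#' @export
normalize_spectrogram <- function(spectrogram) {
  stopifnot(inherits(spectrogram, "sleep_spectrogram"))
  mu <- colMeans(spectrogram$power)
  bad <- which(mu <= 0)
  if (length(bad)) {
    stop("frequency row(s) with non-positive temporal mean power: ",
         paste(spectrogram$freqs[utils::head(bad, 5)], collapse = ", "), " Hz")
  }
  out <- spectrogram
  out$power <- sweep(spectrogram$power, 2, mu, `/`)
  out$normalized <- TRUE
  out
}

#' Canonical frequency bands used by the pipeline
#'
#' Returns the band scheme (Hz): delta 0.5-4, theta 5-12, staging sigma
#' 12-20, high gamma 100-150, EMG 50-500, infraslow-analysis sigma 10.5-16,
#' and spindle sigma 10-16.67.  Any element can be overridden.
#'
#' @param ... named length-2 numeric overrides, e.g. `delta = c(1, 4)`.
#' @return named list of length-2 numeric vectors.
#' @export
band_scheme <- function(...) {
  scheme <- list(delta = c(0.5, 4), theta = c(5, 12), sigma_stage = c(12, 20),
                 gamma = c(100, 150), emg_band = c(50, 500),
                 sigma_infraslow = c(10.5, 16), sigma_spindle = c(10, 16.67))
  over <- list(...)
  for (nm in names(over)) {
    b <- over[[nm]]
    stopifnot(length(b) == 2, b[1] < b[2])
    scheme[[nm]] <- b
  }
  scheme
}
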