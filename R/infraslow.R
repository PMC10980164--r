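# Quantification of the infraslow (~0.02 Hz, ~1 minute period) oscillation
# of EEG sigma power during consolidated NREM sleep: normalized sigma-power
# time course, per-bout power spectral density, strength metric, and peak
# frequency.

#' Normalized sigma-power time course
#'
#' Averages the normalized spectral density over the sigma band (default
#' 10.5-16 Hz) per epoch.  The input must be a normalized spectrogram (every
#' frequency row with temporal mean 1); anything else is rejected.
#'
#' @param normalized_spectrogram output of [normalize_spectrogram()].
#' @param band sigma band in Hz.
#' @return object of class `sigma_timecourse`: list with `times` (s, 2.5 s
#'   step) and `values` (dimensionless).
#' @export
sigma_timecourse <- function(normalized_spectrogram, band = c(10.5, 16)) {
  stopifnot(inherits(normalized_spectrogram, "sleep_spectrogram"))
  mu <- colMeans(normalized_spectrogram$power)
  if (is.null(normalized_spectrogram$normalized) ||
      any(abs(mu - 1) > 1e-8)) {
    stop("spectrogram is not normalized (per-frequency temporal means != 1); ",
         "call normalize_spectrogram() first")
  }
  f <- normalized_spectrogram$freqs
  sel <- f >= band[1] - 1e-9 & f <= band[2] + 1e-9
  if (!any(sel)) stop("sigma band outside the frequency grid")
  structure(list(times = normalized_spectrogram$times,
                 values = rowMeans(normalized_spectrogram$power[, sel,
                                                                drop = FALSE]),
                 step_s = normalized_spectrogram$step_s),
            class = "sigma_timecourse")
}

#' @export
print.sigma_timecourse <- function(x, ...) {
  cat("<sigma_timecourse> ", length(x$values), " epochs, step ", x$step_s,
      " s, mean ", round(mean(x$values), 3), "\n", sep = "")
  invisible(x)
}

#' Infraslow PSD of the sigma-power time course over consolidated NREM bouts
#'
#' For each consolidated NREM bout the sigma series restricted to the bout
#' is mean-removed, Hann-tapered and Fourier-transformed as a single Welch
#' segment (one segment per bout preserves the frequency resolution needed
#' to resolve 0.01 Hz; bouts barely exceed the 100 s that requires).  Bout
#' spectra are linearly interpolated onto the grid of the longest bout and
#' averaged.
#'
#' @param sigma_tc a `sigma_timecourse`.
#' @param consolidated_bouts output of [consolidate_nrem()]; every span must
#'   be at least 120 s.
#' @return object of class `infraslow_psd`: list with `freqs` (Hz),
#'   `density`, `n_bouts`, `strength` (see [infraslow_strength()]) and
#'   `peak_freq_hz` (see [infraslow_peak_frequency()]).
#' @export
infraslow_psd <- function(sigma_tc, consolidated_bouts) {
  stopifnot(inherits(sigma_tc, "sigma_timecourse"))
  dt <- sigma_tc$step_s
  fs <- 1 / dt
  n_avail <- length(sigma_tc$values)
  segs <- list()
  for (i in seq_len(nrow(consolidated_bouts))) {
    i0 <- consolidated_bouts$start_epoch[i]
    i1 <- min(consolidated_bouts$end_epoch[i], n_avail)
    if (i1 - i0 + 1L < 120 / dt) next
    segs[[length(segs) + 1L]] <- sigma_tc$values[i0:i1]
  }
  if (!length(segs)) {
    stop("no consolidated NREM bout of at least 120 s covered by the sigma ",
         "time course")
  }
  one_psd <- function(x) {
    n <- length(x)
    x <- x - mean(x)
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
    X <- stats::fft(x * w)
    nf <- n %/% 2 + 1L
    P <- Mod(X[seq_len(nf)])^2 / (fs * sum(w^2))
    if (nf > 2) P[2:(nf - 1L)] <- 2 * P[2:(nf - 1L)]
    list(freqs = seq(0, fs / 2, length.out = nf), density = P)
  }
  psds <- lapply(segs, one_psd)
  longest <- which.max(vapply(segs, length, integer(1)))
  grid <- psds[[longest]]$freqs
  dens <- vapply(psds, function(p) {
    stats::approx(p$freqs, p$density, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  density <- rowMeans(dens)
  out <- structure(list(freqs = grid, density = density,
                        n_bouts = length(segs)),
                   class = "infraslow_psd")
  out$strength <- infraslow_strength(out)
  out$peak_freq_hz <- infraslow_peak_frequency(out)
  out
}

#' @export
print.infraslow_psd <- function(x, ...) {
  cat("<infraslow_psd> ", x$n_bouts, " bouts, grid step ",
      signif(x$freqs[2] - x$freqs[1], 3), " Hz, peak ",
      signif(x$peak_freq_hz, 3), " Hz, strength ",
      signif(x$strength, 4), "\n", sep = "")
  invisible(x)
}

# trapezoidal area of (freqs, density) over [lo, hi], with linear
# interpolation at the exact band edges
.trapz_band <- function(freqs, density, lo, hi) {
  if (lo < min(freqs) - 1e-12 || hi > max(freqs) + 1e-12) {
    stop("frequency grid does not cover [", lo, ", ", hi, "] Hz")
  }
  inner <- freqs > lo & freqs < hi
  xf <- c(lo, freqs[inner], hi)
  yf <- stats::approx(freqs, density, xout = xf)$y
  sum(diff(xf) * (utils::head(yf, -1) + utils::tail(yf, -1)) / 2)
}

#' Strength of the infraslow rhythm
#'
#' Trapezoidal area under the PSD over 0.01-0.04 Hz minus the area over
#' 0.08-0.12 Hz.  Note the two reference intervals have different widths
#' (0.03 vs 0.04 Hz), so a flat spectrum has slightly negative strength.
#'
#' @param psd an `infraslow_psd`, or any list with `freqs` and `density`.
#' @return scalar strength.
#' @export
infraslow_strength <- function(psd) {
  .trapz_band(psd$freqs, psd$density, 0.01, 0.04) -
    .trapz_band(psd$freqs, psd$density, 0.08, 0.12)
}

#' Peak frequency of the infraslow rhythm
#'
#' Frequency of the maximum density within the search window.  Ties resolve
#' to the lowest frequency.
#'
#' @param psd an `infraslow_psd`.
#' @param search length-2 search window in Hz.
#' @return frequency in Hz.
#' @export
infraslow_peak_frequency <- function(psd, search = c(0.005, 0.12)) {
  sel <- which(psd$freqs >= search[1] - 1e-12 & psd$freqs <= search[2] + 1e-12)
  if (!length(sel)) stop("search window [", search[1], ", ", search[2],
                         "] Hz contains no grid frequency")
  psd$freqs[sel[which.max(psd$density[sel])]]
}
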