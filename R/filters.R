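# Low-level signal-processing primitives: Butterworth low-pass design in
# second-order sections, zero-phase (forward-backward) filtering, topographic
# peak prominence, and coloured-noise synthesis.  None of the installed R
# packages provide these, so they are implemented here and cross-checked
# against an independent reference in the test suite.

#' Design a digital Butterworth low-pass filter in second-order sections
#'
#' Classic analog Butterworth prototype mapped through the bilinear transform
#' with frequency pre-warping.  Only even orders are supported (the pipeline
#' uses order 4 throughout, matching standard practice for physiological
#' low-pass filtering).
#'
#' @param order filter order (even, >= 2).
#' @param fc cutoff frequency in Hz (the -3 dB point).
#' @param fs sampling rate in Hz.
#' @return a list of second-order sections, each a list with numerator `b`
#'   (length 3) and denominator `a` (length 3, `a[1] == 1`).
#' @keywords internal
butter_lowpass_sos <- function(order, fc, fs) {
  stopifnot(order >= 2, order %% 2 == 0, fc > 0, fs > 0, fc < fs / 2)
  warped <- 2 * fs * tan(pi * fc / fs)
  k <- seq_len(order)
  # analog poles on the left-half-plane Butterworth circle
  p_analog <- warped * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # bilinear transform
  p_z <- (2 * fs + p_analog) / (2 * fs - p_analog)
  # pair conjugate poles into biquads; all zeros at z = -1
  idx <- order(Im(p_z))   # conjugates end up symmetric; pair first with last
  p_z <- p_z[idx]
  n_sec <- order / 2
  sos <- vector("list", n_sec)
  for (s in seq_len(n_sec)) {
    p1 <- p_z[s]
    p2 <- p_z[order + 1 - s]
    a1 <- -Re(p1 + p2)
    a2 <- Re(p1 * p2)
    # unity DC gain per section: numerator (1 + z^-1)^2 scaled by den(1)/4
    g <- (1 + a1 + a2) / 4
    sos[[s]] <- list(b = g * c(1, 2, 1), a = c(1, a1, a2))
  }
  sos
}

# steady-state filter state for a unit-step input (one biquad, transposed
# direct form II); returned state reproduces scipy's lfilter_zi behaviour
.biquad_zi <- function(b, a) {
  h <- sum(b) / sum(a)
  z2 <- b[3] - a[3] * h
  z1 <- b[2] - a[2] * h + z2
  c(z1, z2)
}

# run one biquad over x (transposed direct form II) with initial state zi
.biquad_filter <- function(b, a, x, zi = c(0, 0)) {
  n <- length(x)
  y <- numeric(n)
  z1 <- zi[1]; z2 <- zi[2]
  b0 <- b[1]; b1 <- b[2]; b2 <- b[3]; a1 <- a[2]; a2 <- a[3]
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b0 * xi + z1
    z1 <- b1 * xi - a1 * yi + z2
    z2 <- b2 * xi - a2 * yi
    y[i] <- yi
  }
  y
}

#' Apply second-order sections causally
#' @keywords internal
sosfilt <- function(sos, x, zi_scale = NULL) {
  y <- x
  scale <- if (is.null(zi_scale)) 0 else zi_scale
  for (sec in sos) {
    zi <- if (is.null(zi_scale)) c(0, 0) else .biquad_zi(sec$b, sec$a) * scale
    y <- .biquad_filter(sec$b, sec$a, y, zi)
    if (!is.null(zi_scale)) scale <- scale * sum(sec$b) / sum(sec$a)
  }
  y
}

#' Zero-phase (forward-backward) filtering through second-order sections
#'
#' Odd-reflection padding at both ends plus steady-state initial conditions,
#' matching the conventional `filtfilt` approach, so step edges and slow
#' drifts do not ring at the boundaries.  The effective order is twice the
#' design order and the phase response is identically zero.
#'
#' @param sos sections from [butter_lowpass_sos()].
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @keywords internal
sosfiltfilt <- function(sos, x) {
  n <- length(x)
  padlen <- min(n - 1L, 3L * (2L * length(sos) + 1L))
  if (padlen < 1) stop("signal too short for zero-phase filtering")
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  y <- sosfilt(sos, ext, zi_scale = ext[1])
  y <- rev(y)
  y <- sosfilt(sos, y, zi_scale = y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

#' Local maxima with topographic prominence
#'
#' Finds strict local maxima (plateaus report their midpoint) and computes
#' each peak's topographic prominence: its height above the higher of the two
#' lowest saddles separating it from larger terrain on either side (window
#' truncated at the signal edges).
#'
#' @param x numeric signal.
#' @param min_prominence keep only peaks with prominence >= this value.
#' @return data.frame with columns `index` (1-based sample), `height`,
#'   `prominence`, ordered by index.
#' @keywords internal
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(data.frame(index = integer(), height = numeric(),
                               prominence = numeric()))
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      # scan over a possible plateau
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        peaks <- c(peaks, as.integer((i + j) %/% 2))
        i <- j + 1L
      } else {
        i <- j + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  if (!length(peaks)) return(data.frame(index = integer(), height = numeric(),
                                        prominence = numeric()))
  prom <- vapply(peaks, function(p) {
    h <- x[p]
    # walk left until strictly higher terrain (or edge), tracking the minimum
    lmin <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) {
      if (x[i] < lmin) lmin <- x[i]
      i <- i - 1L
    }
    rmin <- h
    i <- p + 1L
    while (i <= n && x[i] <= h) {
      if (x[i] < rmin) rmin <- x[i]
      i <- i + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(index = peaks[keep], height = x[peaks[keep]],
             prominence = prom[keep])
}

#' Gaussian white noise shaped into a frequency band
#'
#' FFT-domain masking of white noise: components outside `[lo, hi]` Hz are
#' zeroed, the result is scaled to unit standard deviation.  Used by the
#' synthetic-data generator to build state-dependent EEG band components.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges (Hz).
#' @return numeric vector of length `n`, sd 1.
#' @keywords internal
band_limited_noise <- function(n, fs, lo, hi) {
  stopifnot(lo < hi, hi <= fs / 2)
  w <- stats::rnorm(n)
  f <- abs(seq(0, fs, length.out = n + 1)[1:n])
  f <- pmin(f, fs - f)
  spec <- stats::fft(w)
  spec[f < lo | f > hi] <- 0
  out <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(out)
  if (s == 0) out else out / s
}

#' 1/f ("pink") noise via FFT amplitude shaping
#' @keywords internal
pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  f <- abs(seq(0, fs, length.out = n + 1)[1:n])
  f <- pmin(f, fs - f)
  shape <- ifelse(f > 0, 1 / sqrt(f), 0)
  out <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  out / stats::sd(out)
}

# Tukey (tapered-cosine) envelope: flat core with cosine ramps covering
# `ramp` of the length at each end; keeps injected bursts at their nominal
# amplitude over the core
tukey_window <- function(n, ramp = 0.25) {
  r <- max(1L, round(ramp * n))
  up <- 0.5 * (1 - cos(pi * (seq_len(r) - 1) / r))
  c(up, rep(1, max(0L, n - 2L * r)), rev(up))[seq_len(n)]
}
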