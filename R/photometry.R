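# Fiber-photometry analysis: dF/F against the 405 nm isosbestic reference,
# prominence-based detection of infraslow-timescale calcium transients,
# state-resolved activity, and transient/microarousal overlap.

#' Construct a photometry trace
#'
#' @param sig465 calcium-dependent (465 nm excitation) fluorescence.
#' @param sig405 isosbestic (405 nm) reference fluorescence.
#' @param fs sampling rate (Hz).
#' @return object of class `photometry_trace`.
#' @export
photometry_trace <- function(sig465, sig405, fs) {
  stopifnot(length(sig465) == length(sig405), fs > 0)
  structure(list(sig465 = as.numeric(sig465), sig405 = as.numeric(sig405),
                 fs = fs, dff = NULL),
            class = "photometry_trace")
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat("<photometry_trace> ", length(x$sig465), " samples at ", x$fs,
      " Hz (", round(length(x$sig465) / x$fs), " s); dF/F ",
      if (is.null(x$dff)) "not yet computed" else "computed", "\n", sep = "")
  invisible(x)
}

#' Compute dF/F from dual-wavelength fluorescence
#'
#' Both channels are zero-phase low-pass filtered at 2 Hz (4th-order
#' Butterworth); the 405 nm reference is fitted to the 465 nm signal by
#' least-squares affine regression (slope + intercept), and
#' dF/F = (F465 - fit) / fit.  The fit absorbs photobleaching and motion
#' artifacts shared by the two wavelengths.
#'
#' @param trace a `photometry_trace`, or a list with `sig465`, `sig405`,
#'   `fs`.
#' @param lowpass_hz low-pass cutoff (Hz).
#' @return the trace with `dff` filled in (and `fit`, the fitted reference).
#' @export
compute_dff <- function(trace, lowpass_hz = 2) {
  s465 <- trace$sig465; s405 <- trace$sig405; fs <- trace$fs
  stopifnot(length(s465) == length(s405), length(s465) > 4 * fs / lowpass_hz)
  if (stats::sd(s405) == 0) {
    stop("405 nm reference channel is constant; cannot fit")
  }
  sos <- butter_lowpass_sos(4, lowpass_hz, fs)
  f465 <- sosfiltfilt(sos, s465)
  f405 <- sosfiltfilt(sos, s405)
  co <- stats::coef(stats::lm.fit(cbind(1, f405), f465))
  fit <- co[1] + co[2] * f405
  if (any(fit <= 0)) {
    stop("fitted reference crosses zero; dF/F undefined (check channel ",
         "scaling)")
  }
  trace$dff <- (f465 - fit) / fit
  trace$fit <- fit
  trace$fit_coef <- c(intercept = unname(co[1]), slope = unname(co[2]))
  trace
}

#' Detect infraslow-timescale calcium transients
#'
#' The dF/F signal is zero-phase low-pass filtered at 1/15 Hz (4th-order
#' Butterworth) and local maxima with topographic prominence of at least
#' `prom_factor` times the 1st-to-99th percentile distance of the dF/F
#' signal are reported.  For numerical conditioning of the very-low-cutoff
#' filter, signals sampled faster than `max_fs` are decimated first (after
#' an anti-alias low-pass).
#'
#' @param dff dF/F vector, or a `photometry_trace` with `dff` computed.
#' @param fs sampling rate (Hz); taken from the trace when one is given.
#' @param cutoff_hz transient-timescale cutoff (Hz), default 1/15.
#' @param prom_factor prominence threshold as a fraction of the p99-p1
#'   distance.
#' @param max_fs decimate above this rate (Hz).
#' @return data.frame of class `transient_events` with `time_s` (peak
#'   time), `prominence`, `height`; attribute `threshold`.
#' @export
detect_transients <- function(dff, fs = NULL, cutoff_hz = 1 / 15,
                              prom_factor = 0.05, max_fs = 100) {
  if (inherits(dff, "photometry_trace")) {
    if (is.null(dff$dff)) stop("call compute_dff() first")
    fs <- dff$fs
    dff <- dff$dff
  }
  stopifnot(!is.null(fs), length(dff) > 15 * fs)
  if (fs > max_fs) {
    dec <- ceiling(fs / max_fs)
    dff <- sosfiltfilt(butter_lowpass_sos(4, fs / dec / 2.5, fs), dff)
    dff <- dff[seq(1, length(dff), by = dec)]
    fs <- fs / dec
  }
  filt <- sosfiltfilt(butter_lowpass_sos(4, cutoff_hz, fs), dff)
  # prominence scale comes from the dF/F distribution itself, not the
  # slow-filtered version used for peak finding
  p <- stats::quantile(dff, c(0.01, 0.99), names = FALSE)
  thr <- prom_factor * (p[2] - p[1])
  pk <- if (thr > 0) find_peaks(filt, min_prominence = thr) else
    find_peaks(filt)[0, ]               # constant signal: no usable scale
  out <- data.frame(time_s = (pk$index - 1) / fs, prominence = pk$prominence,
                    height = pk$height)
  attr(out, "threshold") <- thr
  class(out) <- c("transient_events", "data.frame")
  out
}

#' State-resolved z-scored dF/F activity
#'
#' The dF/F signal is z-scored over the whole recording, then averaged over
#' the samples falling in epochs of each state.  States absent from the
#' hypnogram return NaN.
#'
#' @param dff dF/F vector or a `photometry_trace` with `dff`.
#' @param hypnogram a `hypnogram` sharing the recording's t = 0.
#' @param fs sampling rate; taken from the trace when one is given.
#' @return named numeric vector with means for `W`, `N`, `R`.
#' @export
state_activity <- function(dff, hypnogram, fs = NULL) {
  if (inherits(dff, "photometry_trace")) {
    fs <- dff$fs
    dff <- dff$dff
  }
  stopifnot(!is.null(fs))
  s <- sqrt(mean((dff - mean(dff))^2))   # population SD, as for thresholds
  z <- if (s > 0) (dff - mean(dff)) / s else rep(0, length(dff))
  ep <- attr(hypnogram, "epoch_s") %||% 2.5
  t <- (seq_along(z) - 1) / fs
  epoch <- pmin(floor(t / ep) + 1L, length(hypnogram))
  st <- as.character(hypnogram)[epoch]
  vapply(c(W = "W", N = "N", R = "R"), function(k) {
    if (any(st == k)) mean(z[st == k]) else NaN
  }, numeric(1))
}

#' Overlap between calcium transients and microarousals
#'
#' A transient coincides with a microarousal when its peak time lies within
#' `[start - window_s, start + duration + window_s]` of that MA.  Also
#' reports the transient rate per hour of NREM time when `nrem_hours` is
#' given.
#'
#' @param transients `transient_events` (or data.frame with `time_s`),
#'   time-sorted.
#' @param ma_events data.frame with `start_s`, `duration_s`, time-sorted.
#' @param window_s tolerance window in seconds (default 10 s, the timescale
#'   of the transient kernel).
#' @param nrem_hours optional hours of NREM time for the rate.
#' @return list with `proportion` (coincident fraction; 0 when there are no
#'   MAs), `n_coincident`, `n_transients`, `rate_per_h_nrem`.
#' @export
transient_event_overlap <- function(transients, ma_events, window_s = 10,
                                    nrem_hours = NULL) {
  tt <- transients$time_s
  n <- length(tt)
  hit <- rep(FALSE, n)
  for (j in seq_len(nrow(ma_events))) {
    lo <- ma_events$start_s[j] - window_s
    hi <- ma_events$start_s[j] + ma_events$duration_s[j] + window_s
    hit <- hit | (tt >= lo & tt <= hi)
  }
  list(proportion = if (n) mean(hit) else NaN,
       n_coincident = sum(hit), n_transients = n,
       rate_per_h_nrem = if (is.null(nrem_hours) || nrem_hours <= 0) NaN
       else n / nrem_hours)
}

#' Restrict transients to (MA-bridged) NREM context
#'
#' Keeps transients whose peak time falls inside a NREM span bridged across
#' microarousals — the context in which transient counts and their overlap
#' with MAs are reported (transients during wake reflect tonic arousal
#' activity, not the NREM events of interest).
#'
#' @param transients a `transient_events` data.frame.
#' @param hypnogram a `hypnogram` sharing the recording's t = 0.
#' @param ma_max_s maximum bridgeable wake-run duration (s).
#' @return the filtered `transient_events`.
#' @export
filter_transients_nrem <- function(transients, hypnogram, ma_max_s = 20) {
  spans <- consolidate_nrem(hypnogram, min_span_s = 0, ma_max_s = ma_max_s)
  keep <- vapply(transients$time_s, function(tt) {
    any(spans$start_s <= tt & spans$end_s > tt)
  }, logical(1))
  out <- transients[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- attr(transients, "threshold")
  class(out) <- c("transient_events", "data.frame")
  out
}
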