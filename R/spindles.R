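# Sleep-spindle detection: a 100 ms resolution spectrogram, a bin-wise
# two-criterion candidate test (recording-wide 96th-percentile sigma-peak
# threshold and a sigma / low-frequency peak ratio), and event assembly
# (adjacency merge, < 300 ms gap fusion, > 200 ms duration, and a majority
# in-band peak-frequency requirement).

#' Default spindle-detector parameters
#'
#' @param win_ms analysis window (ms).
#' @param step_ms window step (ms); the detector's temporal resolution.
#' @param sigma_band spindle sigma band in Hz.
#' @param low_band reference low-frequency band in Hz.
#' @param sigma_percentile recording-wide percentile of sigma-peak heights
#'   used as detection threshold.
#' @param peak_ratio required ratio of the sigma peak to the low-band peak.
#' @param fuse_gap_ms events separated by gaps strictly shorter than this
#'   are fused.
#' @param min_dur_ms events of duration less than or equal to this are
#'   discarded.
#' @param freq_fraction minimum fraction of bins whose peak frequency must
#'   lie inside `sigma_band`.
#' @return named list of parameters.
#' @export
spindle_params <- function(win_ms = 600, step_ms = 100,
                           sigma_band = c(10, 16.67), low_band = c(0, 10),
                           sigma_percentile = 96, peak_ratio = 0.5,
                           fuse_gap_ms = 300, min_dur_ms = 200,
                           freq_fraction = 0.5) {
  stopifnot(sigma_percentile > 0, sigma_percentile < 100,
            peak_ratio > 0, peak_ratio <= 1, win_ms > 0, step_ms > 0,
            fuse_gap_ms >= 0, min_dur_ms >= 0,
            freq_fraction > 0, freq_fraction <= 1)
  list(win_ms = win_ms, step_ms = step_ms, sigma_band = sigma_band,
       low_band = low_band, sigma_percentile = sigma_percentile,
       peak_ratio = peak_ratio, fuse_gap_ms = fuse_gap_ms,
       min_dur_ms = min_dur_ms, freq_fraction = freq_fraction)
}

#' High-resolution spectrogram for spindle detection
#'
#' One Hann-tapered spectrum per 600 ms window, windows advancing by 100 ms
#' (500 ms overlap), giving 100 ms temporal resolution.
#'
#' @param eeg numeric EEG signal (µV).
#' @param fs sampling rate (Hz).
#' @param params from [spindle_params()].
#' @return a `sleep_spectrogram` with `step_s = params$step_ms / 1000`.
#' @export
spindle_spectrogram <- function(eeg, fs, params = spindle_params()) {
  nwin <- round(params$win_ms / 1000 * fs)
  if (length(eeg) < nwin) stop("signal shorter than one spindle window (",
                               params$win_ms, " ms)")
  nstep <- round(params$step_ms / 1000 * fs)
  n_times <- (length(eeg) - nwin) %/% nstep + 1L
  starts <- (seq_len(n_times) - 1L) * nstep
  idx <- outer(seq_len(nwin), starts, `+`)
  segs <- matrix(eeg[idx], nrow = nwin)
  segs <- sweep(segs, 2, colMeans(segs))
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nwin) - 1) / nwin))
  X <- stats::mvfft(segs * w)
  nfreq <- nwin %/% 2 + 1L
  P <- (Mod(X[seq_len(nfreq), , drop = FALSE])^2) / (fs * sum(w^2))
  if (nfreq > 2) P[2:(nfreq - 1L), ] <- 2 * P[2:(nfreq - 1L), ]
  structure(list(times = starts / fs,
                 freqs = seq(0, fs / 2, length.out = nfreq),
                 power = t(P), fs = fs,
                 window_s = params$win_ms / 1000,
                 step_s = params$step_ms / 1000),
            class = "sleep_spectrogram")
}

#' Bin-wise spindle candidate detection
#'
#' A 100 ms bin is a candidate iff (1) the height of its maximum spectral
#' peak inside the sigma band strictly exceeds the recording-wide
#' `sigma_percentile`-th percentile of all bins' sigma-peak heights, and
#' (2) that sigma peak strictly exceeds `peak_ratio` times the bin's maximum
#' peak in the low band (0-10 Hz).
#'
#' @param spectrogram output of [spindle_spectrogram()].
#' @param params from [spindle_params()].
#' @return list with `candidate` (logical per bin), `peak_height` (sigma
#'   peak), `peak_freq` (whole-spectrum argmax frequency per bin, used by
#'   the in-band-majority event criterion), `sigma_peak_freq` (in-band
#'   argmax), `threshold`.
#' @export
detect_candidate_bins <- function(spectrogram, params = spindle_params()) {
  f <- spectrogram$freqs
  sig_sel <- f >= params$sigma_band[1] - 1e-9 & f <= params$sigma_band[2] + 1e-9
  low_sel <- f >= params$low_band[1] - 1e-9 & f <= params$low_band[2] + 1e-9
  Psig <- spectrogram$power[, sig_sel, drop = FALSE]
  peak_height <- apply(Psig, 1, max)
  sigma_peak_freq <- f[sig_sel][apply(Psig, 1, which.max)]
  low_peak <- apply(spectrogram$power[, low_sel, drop = FALSE], 1, max)
  # whole-spectrum peak frequency per bin: the in-band-majority criterion
  # discriminates spindle bins (global peak ~12 Hz) from background bins
  # (global peak at low frequencies)
  peak_freq <- f[apply(spectrogram$power, 1, which.max)]
  threshold <- stats::quantile(peak_height, params$sigma_percentile / 100,
                               names = FALSE, type = 7)
  list(candidate = peak_height > threshold &
         peak_height > params$peak_ratio * low_peak,
       peak_height = peak_height, peak_freq = peak_freq,
       sigma_peak_freq = sigma_peak_freq, threshold = threshold)
}

#' Assemble candidate bins into spindle events
#'
#' Adjacent candidate bins form one event; events separated by gaps strictly
#' shorter than `fuse_gap_ms` are fused (the gap counting toward the event's
#' duration); events with duration (bin count x step) of `min_dur_ms` or
#' less are discarded; surviving events must have at least `freq_fraction`
#' of their bins' peak frequencies inside the sigma band.
#'
#' @param candidate logical vector per bin (or the list returned by
#'   [detect_candidate_bins()]).
#' @param per_bin_freqs sigma-band peak frequency per bin (Hz); ignored when
#'   `candidate` is the detector list.
#' @param params from [spindle_params()].
#' @param bin_times optional bin start times in seconds (default the 100 ms
#'   grid).
#' @return data.frame of class `spindle_events` with columns `start_s`,
#'   `end_s`, `duration_ms`, `n_bins`, `mean_freq_hz`.
#' @export
assemble_spindles <- function(candidate, per_bin_freqs = NULL,
                              params = spindle_params(), bin_times = NULL) {
  if (is.list(candidate)) {
    per_bin_freqs <- candidate$peak_freq
    candidate <- candidate$candidate
  }
  step_s <- params$step_ms / 1000
  if (is.null(bin_times)) bin_times <- (seq_along(candidate) - 1L) * step_s
  r <- rle(candidate)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (!nrow(runs)) return(.empty_spindles())
  # fuse runs separated by gaps strictly shorter than fuse_gap_ms
  fused <- runs[1, ]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap_bins <- runs$start[i] - fused$end[nrow(fused)] - 1L
      if (gap_bins * params$step_ms < params$fuse_gap_ms) {
        fused$end[nrow(fused)] <- runs$end[i]
      } else {
        fused <- rbind(fused, runs[i, ])
      }
    }
  }
  n_bins <- fused$end - fused$start + 1L
  dur_ms <- n_bins * params$step_ms
  keep <- dur_ms > params$min_dur_ms
  if (!is.null(per_bin_freqs)) {
    in_band <- vapply(seq_len(nrow(fused)), function(i) {
      fr <- per_bin_freqs[fused$start[i]:fused$end[i]]
      mean(fr >= params$sigma_band[1] - 1e-9 &
             fr <= params$sigma_band[2] + 1e-9)
    }, numeric(1))
    keep <- keep & in_band >= params$freq_fraction
  }
  fused <- fused[keep, , drop = FALSE]
  if (!nrow(fused)) return(.empty_spindles())
  out <- data.frame(
    start_s = bin_times[fused$start],
    end_s = bin_times[fused$end] + step_s,
    duration_ms = (fused$end - fused$start + 1L) * params$step_ms,
    n_bins = fused$end - fused$start + 1L,
    mean_freq_hz = if (is.null(per_bin_freqs)) NA_real_ else
      vapply(seq_len(nrow(fused)), function(i)
        mean(per_bin_freqs[fused$start[i]:fused$end[i]]), numeric(1)))
  rownames(out) <- NULL
  class(out) <- c("spindle_events", "data.frame")
  out
}

.empty_spindles <- function() {
  out <- data.frame(start_s = numeric(), end_s = numeric(),
                    duration_ms = numeric(), n_bins = integer(),
                    mean_freq_hz = numeric())
  class(out) <- c("spindle_events", "data.frame")
  out
}

#' Detect sleep spindles in an EEG signal
#'
#' Convenience wrapper chaining [spindle_spectrogram()],
#' [detect_candidate_bins()] and [assemble_spindles()].  When a hypnogram is
#' supplied, detection is restricted to NREM epochs: candidate bins outside
#' NREM are cleared before assembly (thresholds are still computed on the
#' whole recording).
#'
#' @param eeg numeric EEG signal (µV).
#' @param fs sampling rate (Hz).
#' @param params from [spindle_params()].
#' @param hypnogram optional `hypnogram` for NREM restriction.
#' @return a `spindle_events` data.frame.
#' @export
detect_spindles <- function(eeg, fs, params = spindle_params(),
                            hypnogram = NULL) {
  spg <- spindle_spectrogram(eeg, fs, params)
  cand <- detect_candidate_bins(spg, params)
  if (!is.null(hypnogram)) {
    ep <- attr(hypnogram, "epoch_s") %||% 2.5
    epoch_of_bin <- pmin(floor(spg$times / ep) + 1L, length(hypnogram))
    cand$candidate <- cand$candidate &
      as.character(hypnogram)[epoch_of_bin] == "N"
  }
  assemble_spindles(cand, params = params, bin_times = spg$times)
}

#' Grid-search calibration of spindle-detector parameters
#'
#' The original detector was tuned against a manually annotated recording;
#' absent such annotations this utility scores parameter combinations
#' against ground-truth events (e.g. from [simulate_spindle_eeg()]) by F1
#' with a start-time match tolerance, and returns the grid sorted by score.
#'
#' @param eeg,fs signal and sampling rate.
#' @param truth data.frame with `start_s`, `end_s` of true events.
#' @param grid data.frame of parameter overrides, one row per combination
#'   (columns named as in [spindle_params()]).
#' @param tol_s match tolerance in seconds.
#' @return `grid` with added `precision`, `recall`, `f1`, ordered by
#'   decreasing `f1`.
#' @export
tune_spindle_params <- function(eeg, fs, truth,
                                grid = expand.grid(
                                  sigma_percentile = c(90, 94, 96, 98),
                                  peak_ratio = c(0.3, 0.5, 0.7)),
                                tol_s = 0.3) {
  score <- t(vapply(seq_len(nrow(grid)), function(i) {
    p <- do.call(spindle_params, as.list(grid[i, , drop = FALSE]))
    ev <- detect_spindles(eeg, fs, p)
    m <- match_events(ev, truth, tol_s)
    unlist(m[c("precision", "recall", "f1")])
  }, numeric(3)))
  out <- cbind(grid, score)
  out[order(-out$f1), ]
}

#' Greedy one-to-one matching of detected events to ground truth
#'
#' A detected event matches a true event when their intervals, the true one
#' expanded by `tol_s` on each side, overlap; each true event is consumed by
#' at most one detection.
#'
#' @param detected,truth data.frames with `start_s` and `end_s`.
#' @param tol_s tolerance in seconds.
#' @return list with `n_matched`, `precision`, `recall`, `f1`.
#' @export
match_events <- function(detected, truth, tol_s = 0.3) {
  used <- rep(FALSE, nrow(truth))
  n_matched <- 0L
  for (i in seq_len(nrow(detected))) {
    hit <- which(!used &
                   detected$start_s[i] <= truth$end_s + tol_s &
                   detected$end_s[i] >= truth$start_s - tol_s)
    if (length(hit)) {
      used[hit[1]] <- TRUE
      n_matched <- n_matched + 1L
    }
  }
  precision <- if (nrow(detected)) n_matched / nrow(detected) else NaN
  recall <- if (nrow(truth)) n_matched / nrow(truth) else NaN
  f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0)
    0 else 2 * precision * recall / (precision + recall)
  list(n_matched = n_matched, precision = precision, recall = recall, f1 = f1)
}
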