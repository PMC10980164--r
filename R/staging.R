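# Rule-based sleep staging: per-epoch band-power features, recording-wide
# thresholds, and the Wake/NREM/REM classification rules.

#' Per-epoch staging features from EEG and EMG spectrograms
#'
#' Integrates the staging bands — delta 0.5-4 Hz, theta 5-12 Hz, sigma
#' 12-20 Hz, high gamma 100-150 Hz on the EEG, and 50-500 Hz on the EMG —
#' and forms the theta/delta ratio.  The EMG band's upper edge is clipped to
#' the spectrogram's maximum frequency when the sampling rate does not reach
#' 1 kHz.  Epochs with zero delta power get a theta/delta ratio of 0.
#'
#' @param eeg_spectrogram,emg_spectrogram `sleep_spectrogram` objects on the
#'   same time base.
#' @param bands band scheme from [band_scheme()].
#' @return object of class `stage_features`: data.frame with columns
#'   `delta`, `theta`, `sigma`, `gamma`, `theta_delta_ratio`, `emg_power`;
#'   attribute `epoch_s = 2.5`.
#' @export
extract_features <- function(eeg_spectrogram, emg_spectrogram,
                             bands = band_scheme()) {
  stopifnot(inherits(eeg_spectrogram, "sleep_spectrogram"),
            inherits(emg_spectrogram, "sleep_spectrogram"))
  if (nrow(eeg_spectrogram$power) != nrow(emg_spectrogram$power)) {
    stop("EEG and EMG spectrograms have different numbers of time bins (",
         nrow(eeg_spectrogram$power), " vs ", nrow(emg_spectrogram$power), ")")
  }
  emg_band <- bands$emg_band
  emg_band[2] <- min(emg_band[2], max(emg_spectrogram$freqs))
  delta <- band_power(eeg_spectrogram, bands$delta)
  theta <- band_power(eeg_spectrogram, bands$theta)
  sigma <- band_power(eeg_spectrogram, bands$sigma_stage)
  gamma_band <- bands$gamma
  if (gamma_band[1] > max(eeg_spectrogram$freqs)) {
    gamma <- rep(0, length(delta))   # gamma unresolvable at this fs
  } else {
    gamma_band[2] <- min(gamma_band[2], max(eeg_spectrogram$freqs))
    gamma <- band_power(eeg_spectrogram, gamma_band)
  }
  ratio <- ifelse(delta > 0, theta / delta, 0)
  out <- data.frame(delta = delta, theta = theta, sigma = sigma,
                    gamma = gamma, theta_delta_ratio = ratio,
                    emg_power = band_power(emg_spectrogram, emg_band))
  attr(out, "epoch_s") <- eeg_spectrogram$step_s
  class(out) <- c("stage_features", "data.frame")
  out
}

#' Recording-wide staging thresholds
#'
#' Each feature is split into a "low" and "high" part at its temporal mean;
#' the EMG power and the theta/delta ratio instead use the mean plus one
#' standard deviation (population SD, i.e. divide-by-n: the threshold
#' describes the observed series, not an estimate of a parent distribution).
#'
#' @param features a `stage_features` object (or data.frame with the same
#'   columns), at least 2 epochs.
#' @return named list of scalar thresholds with attribute `rule` naming the
#'   rule per feature.
#' @export
compute_thresholds <- function(features) {
  if (nrow(features) < 2) stop("need at least 2 epochs to set thresholds")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  rule <- c(delta = "mean", theta = "mean", sigma = "mean", gamma = "mean",
            theta_delta_ratio = "mean_plus_sd", emg_power = "mean_plus_sd")
  thr <- lapply(names(rule), function(nm) {
    x <- features[[nm]]
    if (rule[[nm]] == "mean_plus_sd") mean(x) + pop_sd(x) else mean(x)
  })
  names(thr) <- names(rule)
  const <- names(rule)[vapply(names(rule),
                              function(nm) pop_sd(features[[nm]]) == 0,
                              logical(1))]
  if (length(const)) {
    warning("constant feature(s): ", paste(const, collapse = ", "),
            "; nothing exceeds their threshold under strict >")
  }
  structure(thr, rule = rule)
}

#' Classify epochs into Wake / NREM / REM
#'
#' Applies the threshold rules per epoch, "high" meaning strictly greater
#' than the feature's threshold:
#' \enumerate{
#'   \item REM: high theta/delta ratio, low EMG, low delta.
#'   \item NREM: high delta, low theta/delta ratio, low EMG.
#'   \item NREM (sigma variant): low EMG, low delta, high sigma.
#'   \item Wake: low delta, high EMG.
#'   \item Wake (gamma): high gamma — unless already scored REM above.
#' }
#' Epochs matching no rule are undefined and resolved by carrying the
#' previous resolved state forward; leading undefined epochs become Wake.
#'
#' @param features a `stage_features` object.
#' @param thresholds output of [compute_thresholds()].
#' @return object of class `hypnogram`: character vector over
#'   `c("W","N","R")` with attributes `epoch_s` and `start_s`.
#' @export
classify_epochs <- function(features, thresholds) {
  stopifnot(nrow(features) >= 1)
  delta_hi <- features$delta > thresholds$delta
  sigma_hi <- features$sigma > thresholds$sigma
  gamma_hi <- features$gamma > thresholds$gamma
  ratio_hi <- features$theta_delta_ratio > thresholds$theta_delta_ratio
  emg_hi <- features$emg_power > thresholds$emg_power

  st <- rep(NA_character_, nrow(features))
  rem <- ratio_hi & !emg_hi & !delta_hi
  nrem1 <- delta_hi & !ratio_hi & !emg_hi
  nrem2 <- !emg_hi & !delta_hi & sigma_hi
  wake1 <- !delta_hi & emg_hi
  st[rem] <- "R"
  st[is.na(st) & nrem1] <- "N"
  st[is.na(st) & nrem2] <- "N"
  st[is.na(st) & wake1] <- "W"
  st[is.na(st) & gamma_hi] <- "W"
  # fallback: carry previous resolved state; leading undefined -> Wake
  prev <- "W"
  for (i in seq_along(st)) {
    if (is.na(st[i])) st[i] <- prev else prev <- st[i]
  }
  new_hypnogram(st, epoch_s = attr(features, "epoch_s") %||% 2.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a hypnogram
#'
#' @param states character vector over `c("W","N","R","U")`.
#' @param epoch_s epoch length in seconds.
#' @param start_s recording-start offset of the first epoch.
#' @return a `hypnogram` object.
#' @export
new_hypnogram <- function(states, epoch_s = 2.5, start_s = 0) {
  states <- as.character(states)
  if (!length(states)) stop("hypnogram must be nonempty")
  bad <- setdiff(unique(states), c("W", "N", "R", "U"))
  if (length(bad)) stop("unknown state token(s): ", paste(bad, collapse = ", "))
  structure(states, epoch_s = epoch_s, start_s = start_s, class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = c("W", "N", "R", "U")))
  cat("<hypnogram> ", length(x), " epochs of ", attr(x, "epoch_s"),
      " s (", length(x) * attr(x, "epoch_s") / 3600, " h): ",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
`[.hypnogram` <- function(x, i) {
  new_hypnogram(unclass(x)[i], epoch_s = attr(x, "epoch_s"),
                start_s = attr(x, "start_s"))
}
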