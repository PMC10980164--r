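#' @keywords internal
"_PACKAGE"

#' Stage a recording end to end
#'
#' Convenience chain: EEG and EMG spectrograms ([compute_spectrogram()]),
#' per-epoch features ([extract_features()]), recording-wide thresholds
#' ([compute_thresholds()]) and the rule classifier ([classify_epochs()]).
#'
#' @param recording a `sleep_recording`.
#' @param bands band scheme from [band_scheme()].
#' @return list with `hypnogram`, `features`, `thresholds`,
#'   `eeg_spectrogram`, `emg_spectrogram`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_hypnogram(sim_config(duration_s = 600, fs_eeg = 500))
#' rec <- synthesize_signals(sim$hypnogram, sim$config)$recording
#' staged <- stage_recording(rec)
#' print(staged$hypnogram)
#' }
stage_recording <- function(recording, bands = band_scheme()) {
  eeg_spg <- compute_spectrogram(recording$eeg, recording$fs)
  emg_spg <- compute_spectrogram(recording$emg, recording$fs)
  features <- extract_features(eeg_spg, emg_spg, bands)
  thresholds <- compute_thresholds(features)
  list(hypnogram = classify_epochs(features, thresholds),
       features = features, thresholds = thresholds,
       eeg_spectrogram = eeg_spg, emg_spectrogram = emg_spg)
}

#' Infraslow sigma-rhythm analysis of a recording
#'
#' Chains [normalize_spectrogram()], [sigma_timecourse()],
#' [consolidate_nrem()] and [infraslow_psd()] on an already-computed EEG
#' spectrogram and hypnogram.
#'
#' @param eeg_spectrogram a `sleep_spectrogram` of the EEG.
#' @param hypnogram a `hypnogram` on the same time base.
#' @param band sigma band (Hz) for the time course.
#' @return list with `psd` (an `infraslow_psd`), `sigma_tc`, `bouts`.
#' @export
infraslow_analysis <- function(eeg_spectrogram, hypnogram,
                               band = c(10.5, 16)) {
  stc <- sigma_timecourse(normalize_spectrogram(eeg_spectrogram), band)
  bouts <- consolidate_nrem(hypnogram)
  list(psd = infraslow_psd(stc, bouts), sigma_tc = stc, bouts = bouts)
}
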