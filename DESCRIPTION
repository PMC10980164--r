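Package: sleeprhythms
Title: Rodent Sleep Staging, Infraslow Sigma Rhythm, Spindle and
    Fiber-Photometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for rodent EEG/EMG sleep recordings:
    Welch spectrograms at 2.5 s epoch resolution, rule-based Wake/NREM/REM
    staging from band-power thresholds, microarousal and bout-architecture
    statistics, quantification of the infraslow (~0.02 Hz) oscillation of
    EEG sigma power within consolidated NREM bouts, percentile-threshold
    sleep-spindle detection, fiber-photometry dF/F computation against a
    405 nm isosbestic reference with prominence-based calcium-transient
    detection, and classification of sound-evoked arousal trials.  Includes
    a deterministic synthetic-data generator that emulates the statistical
    structure of such recordings with ground-truth labels, so every stage
    is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
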