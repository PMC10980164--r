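---
title: "Sleep staging, infraslow sigma rhythm, spindles and photometry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep staging, infraslow sigma rhythm, spindles and photometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleeprhythms)
```

This vignette documents the models and conventions behind each stage of the
pipeline, the tunable parameters with their defaults and units, what the
synthetic-data generator does and does not emulate, and the numerical
choices a maintainer would want stated.

## Time and epoch conventions

All timestamps are seconds from recording start, 0-based.  Epochs are 2.5 s
half-open intervals `[2.5*(i-1), 2.5*i)`.  Spectrogram columns are stamped
with the *start* of their 5 s analysis window, so epoch `i`'s features
summarise `[2.5*(i-1), 2.5*(i-1)+5)`: each feature column looks 2.5 s into
the next epoch, which is inherent to half-overlapping 5 s windows at 2.5 s
resolution.  A spectrogram therefore has one column fewer than the
recording has epochs.

## Spectral estimation

`compute_spectrogram()` estimates one PSD per 5 s window by Welch's method:
four half-overlapping 2 s subwindows, each mean-detrended (the minimal
detrend; no slope removal, no notch filtering, signals enter unfiltered),
tapered with a periodic Hann window, one-sided density scaling.  The
frequency grid is `1/2 s = 0.5` Hz without zero padding.  `band_power()`
sums density over all bins inside the closed interval `[lo, hi]` times the
0.5 Hz bin width; both edge bins are included because band limits are
stated inclusively.  On a flat 1 µV²/Hz spectrum the δ band `[0.5, 4]`
therefore integrates 8 bins to 4.0 µV² rather than the ideal-integral
3.5 µV²; the convention is uniform across all bands, and every threshold
that consumes band powers is computed under the same convention, so no
comparison is biased by it.

## Staging

Features per epoch: δ, θ, σ (12–20 Hz) and high-γ EEG band powers, the θ/δ
ratio (0 where δ power is 0) and EMG power over 50–500 Hz.  When the
sampling rate cannot resolve a band (e.g. EMG above Nyquist at 500 Hz
sampling), the band's upper edge is clipped to the grid maximum; γ is set
to 0 if entirely unresolvable.  Thresholds: temporal mean per feature, mean
plus one *population* (divide-by-n) standard deviation for EMG and θ/δ —
the threshold describes the observed series, not an estimate of a parent
distribution.  "High" is strictly greater than the threshold; ties are
"low", making the classifier deterministic.

Rules are applied in the order REM, NREM (primary), NREM (σ variant), Wake
(EMG), Wake (γ); the order mirrors the prose that defines them, and the γ
rule explicitly yields to REM.  Epochs matching no rule carry the previous
resolved state forward (leading undefined epochs become Wake); no undefined
epoch survives.  The classical manual-verification pass over the automatic
scoring is out of scope, so the stand-in for scoring quality is recovery of
the generator's ground truth: ≥ 90 % epoch accuracy at the default
signal-to-noise (the tests measure ~92–99 % over seeds).  The threshold
method assumes a recording long enough to contain a representative mix of
states — on very short or single-state recordings the recording-wide means
are not meaningful separators, which is why the recovery experiments use
one-hour recordings.

## Architecture

Bouts are maximal same-state runs.  A microarousal is a wake run of ≤ 20 s
(inclusive) with NREM immediately on both sides; wake at a recording edge
or flanking REM does not count, since MAs are defined within NREM sleep.
MA wake time still counts toward the wake percentage — the accounting
follows the labels.  Consolidated NREM bouts bridge runs across qualifying
MAs and keep bridged spans ≥ 120 s; the span *includes* the embedded MA
time ("bouts lasting at least 120 s, possibly interrupted by MAs" reads as
span).  Episode frequency is denominated per hour of recording; the MA rate
per hour of NREM time.  Both conventions are stated in the outputs.

## Infraslow sigma rhythm

The spectrogram is normalized by each frequency's temporal mean and σ power
is the mean normalized density over 10.5–16 Hz (the infraslow analysis band
deliberately differs from the 12–20 Hz staging band; both are configurable
and no reconciliation is attempted).  For each consolidated NREM bout the σ
series (0.4 Hz sampling) is mean-removed, Hann-tapered and transformed as a
*single* Welch segment: bouts barely exceed the ~100 s needed to resolve
0.01 Hz, so splitting them would destroy the resolution the strength metric
needs.  Bout spectra are linearly interpolated onto the grid of the longest
bout and averaged.  Strength is the trapezoidal PSD area over 0.01–0.04 Hz
minus that over 0.08–0.12 Hz — note the reference interval is wider
(0.04 vs 0.03 Hz), so a flat spectrum has slightly negative strength; the
metric is linear in the PSD.  The peak frequency is the argmax over
0.005–0.12 Hz, ties resolving to the lowest frequency.

## Spindle detection

A 600 ms window advancing by 100 ms gives the 100 ms detector resolution
(Hann taper per window; the taper is a choice, stated here).  A bin is a
candidate when (1) its maximum σ-band (10–16.67 Hz) density strictly
exceeds the recording-wide 96th percentile of all bins' σ peaks and (2)
that peak strictly exceeds half the bin's 0–10 Hz peak.  Adjacent
candidates merge; gaps strictly below 300 ms fuse (gap bins count toward
duration — bins are the detector's time unit); events with
`bins × 100 ms ≤ 200 ms` are discarded; and at least half of an event's
bins must have their *whole-spectrum* peak frequency inside 10–16.7 Hz.
The whole-spectrum reading is deliberate: an argmax restricted to the σ
band is always in band and would make the criterion vacuous, whereas the
global peak separates spindle bins from low-frequency-dominated background.
When a hypnogram is supplied, candidates outside NREM are cleared before
assembly (thresholds still come from the whole recording).

The original detector's parameters were tuned against manual annotations
that are not available here; the defaults are taken as the stated optimized
values and `tune_spindle_params()` provides an F1 grid search against
synthetic ground truth instead.  On a pink-noise background with injected
12 Hz bursts at 5× the background σ-band RMS, precision and recall exceed
0.95; at exactly 3× the detector is marginal (~0.6–0.8) because the 96th
percentile threshold then falls inside the overlap of the burst and
background peak-height distributions — detectable spindles must clearly
exceed the background, as they do in real recordings.

## Photometry

Both channels are low-passed at 2 Hz (4th-order Butterworth) before the
405→465 nm fit; "linear regression" is implemented as affine (slope +
intercept).  Zero-phase forward–backward filtering is used for *both*
filters, not only the 1/15 Hz one, so no stage introduces phase lag.
ΔF/F = (F465 − fit)/fit.  Transients are strict local maxima of the
1/15 Hz-filtered ΔF/F with topographic prominence ≥ 0.05 × (p99 − p1) *of
the ΔF/F signal itself* — the percentile scale comes from the unfiltered
(2 Hz-band) ΔF/F, which is what "the distribution of the ΔF/F signal"
denotes; a constant signal has no usable scale and yields no transients.
The detector is affine-invariant by construction.  Signals sampled above
100 Hz are decimated first (after an anti-alias low-pass) for numerical
conditioning of the very-low-cutoff filter; the factor is recorded in the
decimation arithmetic.  Transient counts and MA overlap are reported for
transients inside MA-bridged NREM spans (`filter_transients_nrem()`),
matching the "transients during NREM" framing of those statistics; the
tonic wake elevation produces legitimate peaks that are not NREM events.
The MA-coincidence window defaults to 10 s — the transient kernel's own
timescale — and is configurable and reported.

Butterworth design, zero-phase filtering and topographic prominence are
implemented in the package (no installed R package provides them) and are
verified in the test suite against values frozen from an independent
reference implementation.

## Sound-evoked arousals

A trial is eligible when the animal is in NREM at tone onset and the
MA-bridged NREM time *up to the onset* exceeds 120 s (strictly).  Whether
the original criterion means pre-onset time or whole-episode duration is
ambiguous; pre-onset is the default because it is causally available at
stimulus time, and `eligibility = "episode"` switches to the whole bridged
span.  "Woke up in response to the tone" is any wake epoch within the 20 s
tone window; no latency criterion is printed anywhere, so none is invented.
Pre-tone σ traces are aligned over `[-60 s, 0)` and averaged per class;
`pre_tone_slope()` fits the final 15 s, roughly the last quarter of the
~50 s infraslow period, where the descending-phase signature concentrates.

## Synthetic data: what it emulates, and what a green test establishes

The generator emulates: exponential-dwell semi-Markov state sequences (REM
entered only from NREM; wake 180 s, NREM 240 s, REM 75 s means; NREM ends
in REM with probability 0.35, REM in wake with 0.8 — occupancy ≈ 39/55/6 %,
a plausible mouse light-phase mix); MAs inserted into NREM runs at 0.8 per
NREM minute, 2.5–12.5 s; state-switched band-limited Gaussian EEG
components (δ-dominant NREM at ~45 µV component amplitude, θ-dominant REM,
broadband + γ wake) and EMG noise with wake ≫ NREM ≥ REM tone; σ-band
amplitude modulated as `sqrt(1 + depth·sin(2πft))` during NREM (f = 0.02 Hz,
depth 0.6) so σ *power* oscillates at the stated frequency and depth;
Tukey-enveloped 12 Hz spindle bursts at 5 per NREM minute, 500–800 ms;
dual-wavelength photometry sharing an exponential bleach (τ = 3000 s) and
slow motion noise, with ~10 s (FWHM) transient kernels at 1 per NREM minute
plus probability 0.9 at each MA onset (MAs are typically accompanied by
noradrenergic transients, and the recovery property is only consistent
when the unaccompanied MA is the exception); uniform 4–20 min tone gaps.
Natural wake dwells are kept above 22.5 s so that sub-20 s wake comes only
from the explicit MA process and every brief wake intrusion has ground
truth.

It does **not** emulate: 1/f spectral slopes within states (components are
flat within bands), volume conduction or electrode artifacts, state
transition dynamics faster than one epoch, REM theta phase structure,
bleaching nonlinearity beyond a single exponential, or hemodynamic
contamination of the photometry.  A green recovery test therefore
establishes that each algorithm inverts the stated statistical structure at
realistic SNR — not that it reproduces any particular animal's numbers.
Dedicated benchmarks (pink-noise spindle EEG, phase-coupled arousal
sessions) exercise single stages under the structure their property
statements assume.

## Numerical choices and degenerate inputs

* Quantile type 7 (R default) for the spindle percentile; strict `>`
  comparisons throughout, so identical bins yield no candidates.
* Trapezoidal integration with interpolation at exact band edges for the
  infraslow areas.
* Filter state initialisation reproduces steady state for a step input;
  odd-reflection padding at the signal ends.
* Degenerate inputs error early and name the offender: NaN in a signal
  (first index), a constant 405 nm reference, a zero-mean spectrogram row
  (its frequency), unknown hypnogram tokens (their line on read).
* All randomness flows from explicit integer seeds; generator functions
  call `set.seed()` internally and are reproducible bit for bit.

## Known limitations

* The staging thresholds are recording-wide; recordings dominated by a
  single state defeat them (as they would the original procedure).
* EDF support covers continuous 16-bit recordings with per-signal scaling —
  the layout the pipeline's instruments produce — not the discontinuous or
  annotation-bearing EDF+ variants.
* Cross-system clock alignment between electrophysiology and photometry is
  assumed given (shared t = 0); no resynchronisation is attempted.
* The infraslow PSD uses one segment per bout; very long bouts (> 20 min)
  would admit multi-segment averaging that is not implemented.
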