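---
title: "Methods: closed-loop FES phase control and cycle-locked EEG analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop FES phase control and cycle-locked EEG analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fesloop)
```

## The system

`fesloop` models a closed-loop lower-limb neurorehabilitation interface.
A single inertial sensor strapped to the leg reports two acceleration
components, `ax` and `ay`, at a nominal 20 Hz. Their ratio encodes the
orientation of the segment in the sagittal plane: the package computes

\[
\theta = \operatorname{atan2}(a_x, a_y) \cdot 180/\pi \in (-180, 180]\,
\text{degrees.}
\]

The two-argument arctangent is essential: the plain ratio arctangent is
confined to (−90°, 90°), while the pedaling phases live near ±180°.
The angle is classified into named movement phases — two for pedaling
(flexion 150–175°, channels 1–2; extension −179 to −150°, channels 3–4),
four for gait (initial contact, mid-stance, terminal stance, initial
swing, each a muscle group on both legs across 8 channels). Each phase
triggers a set of stimulation channels; the controller emits one command
per sample. Stimulation itself is a charge-balanced symmetric biphasic
rectangular pulse train — protocol settings 35 Hz repetition, 300 µs per
phase, 75 % of the channel maximum.

Cortical evaluation is movement-cycle-locked: EEG (16 channels, 10–20
montage, 512 Hz) is re-referenced to the common average, band-passed
8–45 Hz, cut into cycles at the IMU-derived boundaries, resampled to a
0–100 % cycle grid, and summarized as relative power in dB versus a rest
baseline, per electrode and per band (mu 8–13 Hz, low beta 13–20 Hz,
high beta 20–30 Hz), plus Morlet time–frequency maps at Cz.

## Angle processing and cycle segmentation

`unwrap_angle()` removes the ±180° discontinuities so revolutions can be
counted. `segment_cycles()` places a boundary at each upward crossing of a
reference angle (default 0°) in the unwrapped trace. Crossings are
detected as *first passages through the levels* `ref + 360k` rather than
local sign changes: with the realistic noise level (σ = 0.05 g at 20 Hz,
about 3° of angle jitter against ~6° of progression per sample), local
sign-change detection occasionally double-counts a crossing, which would
bias the cadence estimate upward by several percent. First-passage
detection yields exactly one boundary per revolution by construction;
boundary times are refined by linear interpolation between the bracketing
samples, which is exact for a locally linear angle.

Cadence is `1/mean(periods)`. No smoothing is applied to θ before
classification by default (an optional resampling helper exists for
irregular timestamps); the dwell debounce below handles boundary chatter
instead.

## Controller semantics and safety

The controller is a small finite-state machine (`step_controller()`):

* **Dwell debounce** (`min_dwell_s`, default 0.1 s): a phase transition is
  honoured only after the controller has spent `min_dwell_s` in its
  current phase. This bounds the transition rate when the angle jitters at
  a range boundary. 0.1 s is two IMU samples at 20 Hz — short enough not
  to delay genuine transitions (phases last ≥ 0.3 s at the observed
  cadences), long enough to suppress chatter.
* **Gaps command silence**: the pedaling ranges cover only 56° of the
  circle; between them the controller emits explicit all-off commands
  rather than holding the last command, matching alternating on/off
  channel activation traces.
* **Emergency stop** is a latch: once triggered, every later command is
  all-off regardless of the angle until an explicit reset. The property
  tests drive randomized angle sequences with stops and resets injected at
  random times and assert that no non-empty channel set ever follows a
  stop before its reset.
* **Frequency lock**: `enforce_frequency_lock()` clamps any requested
  command/stimulation rate to the configured ceiling, the software
  analogue of a firmware maximum-frequency lock.

Gait angle ranges are therapist-adjustable in the field, so
`build_gait_config()` takes them as an argument; its defaults simply
quarter the circle and are a software default, not a clinical value.

## Pulse trains

`generate_pulse_train()` synthesizes the waveform on a 100 kHz grid
(30 samples per 300 µs phase): positive phase, then an equal negative
phase, no interphase gap, amplitude ±intensity/100 in normalized units.
Pulse morphology is not uniquely determined by PWM-driven H-bridge
hardware; the symmetric biphasic rectangle is the standard charge-balanced
choice, and charge balance holds exactly by construction (equal sample
counts per phase; trailing pulses that would not fit are dropped whole).
The parameter validator rejects configurations whose biphasic pulse
cannot fit inside one repetition period and synthesis rates below
20 samples per phase.

## The synthetic data generators

The motion simulator produces `ax = sin θ(t) + ε`, `ay = cos θ(t) + ε`
with independent Gaussian noise, where θ advances 360° per cycle period.
Pedaling uses uniform angular velocity; gait spends 60 % of the period on
a stance half-circle and 40 % on the swing half-circle, reproducing the
stance/swing asymmetry of walking while keeping the ground truth
analytic. Defaults mirror the acquisition conditions: 20 Hz sampling,
cycle periods 2.5 s (gait, 0.4 Hz) and 5/3 s (pedaling, 0.6 Hz) in the
examples and tests, noise σ = 0.05 g for the noisy conditions.

The EEG generator builds each channel as

* a 1/f background (spectrally shaped white noise, σ = 2 µV, slope
  clamped below 0.5 Hz),
* a **mu component**: Gaussian noise spectrally flat across exactly
  8–13 Hz, σ = 20 µV at Cz,
* a **beta component**: flat across 20–30 Hz, σ = 10 µV at Cz.

Component amplitudes fall off exponentially with 10–20 scalp distance
from Cz (length scale 0.5 head radii), making the sensorimotor rhythms
Cz-focal. During movement (between the first and last cycle boundary) the
mu power at Cz changes by `erd_db_at_cz` dB; the dB modulation decays
from Cz with length scale 0.3. Two design choices matter for parameter
recovery and were made deliberately:

1. The rhythms are *band-filling noise*, not sinusoids: the band summary
   is the mean dB across band frequency bins, which equals the injected
   dB only if the component dominates the background across the whole
   band.
2. The rhythms are Cz-focal: the common average subtracts 1/16 of every
   channel, so channels with Cz-sized unmodulated rhythms would leak an
   opposing bias of ~0.5 dB into the Cz estimate; with the amplitude
   falloff the leakage bias stays below 0.1 dB.

An optional stimulation artifact mixes a low-pass-filtered (200 Hz
Butterworth, zero phase) replica of the commanded pulse train into all
channels during commanded-on intervals; no empirical value for its
amplitude is available, so it defaults to off.

What the generator does **not** emulate: eye/muscle artifacts, electrode
impedance drift, line noise, volume-conduction correlations between
channel backgrounds, nonstationary rhythm amplitudes, or gait-cycle
sub-structure in the rhythms beyond the on/off movement envelope. Passing
the recovery tests therefore demonstrates that the *pipeline* is
calibrated and unbiased under its stated assumptions — not that real
recordings with artifacts would yield ±0.5 dB accuracy.

## Spectral pipeline choices

* **Filter**: 4th-order Butterworth band-pass applied forward–backward
  (`signal::filtfilt`), i.e. zero phase, so cycle-locked features are not
  shifted; measured attenuation is ≥ 20 dB at half the low edge and at
  the high edge + 10 Hz.
* **Periodogram** (`power_spectrum()`): one-sided, normalised so total
  power equals the time-domain variance (population denominator), checked
  to 10⁻⁶ relative error.
* **Rest and task spectra**: Welch averaging of Hann-windowed 2 s
  segments with 50 % overlap (0.5 Hz resolution at 512 Hz). The task
  spectrum is estimated over the movement span (first to last cycle
  boundary) so the estimate and the generator's modulation envelope refer
  to the same samples.
* **Morlet CWT** (`morlet_cwt()`): 6-cycle complex Morlet, default grid
  8–45 Hz in 0.5 Hz steps, FFT convolution with zero padding. Wavelets
  are L1-normalised so a stationary unit tone produces the same ridge
  power at every analysis frequency; unit-energy normalisation would tilt
  power toward low frequencies and shift ridge peaks by half a bin.
* **dB conventions**: power ratios, `10·log10`. Two references are
  implemented and selected by the function used: `relative_power_db()`
  against the rest-period spectrum (spectra and topographies), and
  `grand_average()` against the movement-cycle mean power per frequency
  (time–frequency maps). The cycle-mean reference is applied on the dB
  scale (geometric-mean power), which makes every frequency row average
  to exactly 0 dB — the defining property of a cycle-relative map.
* **Trial handling**: cycles shorter than two samples are dropped;
  cycles whose period deviates from the median by more than 3 scaled
  median absolute deviations are rejected as outliers (counts reported as
  attributes and a warning). When most periods are identical the MAD is
  zero and rejection is skipped rather than discarding everything.
* **Degenerate inputs**: both accelerometer components zero is a hard
  error naming the sample index; a constant angle yields an empty
  segmentation (not an error); empty segmentations make the cadence
  undefined (error) and yield empty trial matrices; non-positive
  reference power is rejected before any log is taken.

## Problem sizes

The test suite works at sizes where every property is decisive but cheap:
30–60 s motion traces for phase counts and cadence recovery, 120 s
EEG sessions (16 × 61 440 samples) for the ±0.5 dB modulation-recovery
property at injected −6, −3, 0 and +3 dB, and 2–4 s tones for the
spectral oracles. The full suite runs in well under a minute on one CPU;
`scripts/acceptance.R` recomputes the headline numbers in a few seconds.

## Known limitations

* The EDF reader/writer is minimal: one sampling rate for all signals,
  1 s records, 16-bit EDF without EDF+ annotations.
* The controller processes samples sequentially in R; at 20 Hz input this
  is orders of magnitude faster than real time, but the package makes no
  hard real-time claims.
* No artifact-removal stage (e.g. ICA) is implemented; the evaluation
  pipeline applies only CAR and the band-pass, and the simulator's
  artifact model is correspondingly simple.
* Gait-phase angle ranges are task configuration, not estimates; the
  package does not learn ranges from data.
* Statistical inference across subjects or sessions is out of scope; the
  pipeline produces descriptive spectra and maps.
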