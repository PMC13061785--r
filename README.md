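# fesloop

Closed-loop functional electrical stimulation (FES) control from inertial
signals, with a movement-cycle-locked EEG evaluation pipeline — exercised
entirely on synthetic signals.

## What problem this addresses

In lower-limb neurorehabilitation after incomplete spinal cord injury, a
human–machine interface can assist residual movement: a single inertial
sensor on the leg measures two acceleration components, their ratio gives
the segment angle

θ = atan2(aₓ, a_y) · 180/π ∈ (−180°, 180°],

the angle is classified into movement phases, and each phase triggers a set
of stimulation channels in real time. Pedaling uses two phases (flexion
150–175°, channels 1–2: right quadriceps + left hamstring; extension −179°
to −150°, channels 3–4: left quadriceps + right hamstring); gait uses four
(initial contact, mid-stance, terminal stance, initial swing) over 8
channels on both legs. Stimulation is a charge-balanced biphasic pulse
train (protocol settings: 35 Hz, 300 µs per phase, 75 % of the channel
maximum). Whether the loop works is judged kinematically (cycle
consistency, cadence ≈ 0.4 Hz for gait, ≈ 0.6 Hz for pedaling) and
cortically: EEG is common-average referenced, band-passed 8–45 Hz,
segmented at the IMU-derived cycle boundaries, normalised to 0–100 % of
the cycle, and summarized as relative power in dB versus rest in the mu
(8–13 Hz), low-beta (13–20 Hz) and high-beta (20–30 Hz) bands, plus Morlet
time–frequency maps at Cz.

`fesloop` implements all of that as tested R code for researchers and
engineers building or evaluating such interfaces: the angle/segmentation
kinematics, the phase controller with software safety interlocks
(latched emergency stop, frequency lock, dwell debouncing), biphasic
pulse-train synthesis and verification, synthetic IMU/EEG generators with
analytic ground truth, and the spectral pipeline. No hardware is
required; the simulators stand in for the sensor, stimulator and
amplifier.

## Worked example

```r
library(fesloop)

# 60 s noisy pedaling session through the closed loop
motion  <- motion_sim_config("pedaling", cycle_period = 5/3, duration = 60,
                             noise_sigma = 0.05, seed = 42)
eeg     <- eeg_sim_config(erd_db_at_cz = -3, seed = 43)  # 3 dB mu ERD at Cz
session <- run_closed_loop_session(motion, build_pedaling_config(), eeg)
session
#> <session_record> 60.0 s, 1201 IMU samples, 34 cycle(s), 1201 command(s),
#>   EEG 16 ch x 30720 samples

estimate_frequency(session$segmentation)[1]
#> [1] 0.6000556          # configured cadence 0.6 Hz recovered

# recover the injected desynchronization from the EEG
rest <- simulate_rest(eeg, 60)
res  <- erd_analysis(session$eeg, rest, session$segmentation)
mu   <- res$band_summaries$mu
head(mu[order(mu$power_db), ], 3)
#>   electrode   power_db
#> 8        Cz -2.9691122   # injected -3 dB, Cz-focal as simulated
#> 6       FC2 -0.9956308
#> 5       FC1 -0.8875837

# protocol stimulation waveform round trip
train <- generate_pulse_train(stim_params(35, 300, 75), duration = 1)
c(rate_hz = measure_pulse_rate(train), width_us = measure_pulse_width(train))
#>  rate_hz width_us
#> 35.00031      300
```

The cadence line says the segmentation pipeline recovered the simulated
0.6 Hz pedaling frequency from the noisy accelerometer trace; the mu table
shows the pipeline reading back the injected −3 dB mu-band power change at
Cz (and only there); the last line verifies the synthesized pulse train
against its configured repetition rate and pulse width.

Batch use mirrors the same functions: `cmd_simulate()` (YAML config →
IMU/EDF/CSV session files), `cmd_run_loop()` (IMU CSV + task YAML →
command log) and `cmd_analyze()` (EDF + events → spectra, band summaries,
Cz time–frequency map), also reachable from a shell via
`inst/cli/fesloop`.

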