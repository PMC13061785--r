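Package: fesloop
Title: Closed-Loop Functional Electrical Stimulation Control from Inertial
    Signals with Cycle-Locked EEG Spectral Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating a closed-loop lower-limb
    neurorehabilitation interface. Converts two-axis accelerometer recordings
    into segment angles, segments them into movement cycles and estimates
    cadence; classifies angles into gait or pedaling phases and emits
    multi-channel functional electrical stimulation (FES) commands with
    software safety interlocks (emergency stop latch, frequency lock,
    transition debouncing); synthesizes charge-balanced biphasic pulse
    trains; simulates cyclic inertial traces and 16-channel EEG with 1/f
    background and cycle-locked mu/beta power modulation; and implements a
    movement-cycle-locked EEG evaluation pipeline (common average reference,
    zero-phase band-pass filtering, cycle-normalised trials, periodogram and
    Morlet wavelet spectra, relative power in dB versus rest, and band
    topography summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
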