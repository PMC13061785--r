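# Shared fixtures: small traces and recordings built in code.

imu_df <- function(t, ax, ay) data.frame(t = t, ax = ax, ay = ay)

# Noise-free trace sweeping the angle linearly from `from` to `to` degrees.
sweep_trace <- function(from, to, duration = 10, rate = 20) {
  t <- seq(0, duration, by = 1 / rate)
  theta <- seq(from, to, length.out = length(t)) * pi / 180
  imu_df(t, sin(theta), cos(theta))
}

# Tiny EEG recording with deterministic content.
toy_recording <- function(nch = 3, n = 1024, rate = 512, seed = 1) {
  withr::with_seed(seed, {
    eeg_recording(matrix(rnorm(nch * n), nrow = nch), rate,
                  paste0("ch", seq_len(nch)))
  })
}

sine_recording <- function(freq, nch = 2, dur = 4, rate = 512,
                           labels = paste0("ch", seq_len(nch))) {
  t <- (seq_len(dur * rate) - 1) / rate
  eeg_recording(matrix(rep(sin(2 * pi * freq * t), each = nch), nrow = nch),
                rate, labels)
}
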