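test_that("common average reference removes the channel mean exactly", {
  rec <- eeg_recording(matrix(3, nrow = 4, ncol = 10), 512,
                       paste0("ch", 1:4))
  out <- common_average_reference(rec)
  expect_true(all(out$data == 0))

  ab <- toy_recording(nch = 2, n = 256)
  car <- common_average_reference(ab)
  expect_equal(car$data[1, ], (ab$data[1, ] - ab$data[2, ]) / 2)
  expect_equal(car$data[2, ], (ab$data[2, ] - ab$data[1, ]) / 2)

  r <- toy_recording(nch = 5, n = 512)
  once <- common_average_reference(r)
  expect_lt(max(abs(colSums(once$data))), 1e-10)
  twice <- common_average_reference(once)
  expect_equal(twice$data, once$data, tolerance = 1e-12)

  expect_error(common_average_reference(
    eeg_recording(matrix(1, 1, 10), 512, "Cz")), "at least 2")
})

test_that("band-pass keeps the passband and attenuates out-of-band tones", {
  rms <- function(x) sqrt(mean(x^2))
  inband <- bandpass_filter(sine_recording(20), 8, 45)
  expect_lt(abs(rms(inband$data[1, ]) - rms(sine_recording(20)$data[1, ])) /
              rms(sine_recording(20)$data[1, ]), 0.05)
  low <- bandpass_filter(sine_recording(2), 8, 45)
  expect_lt(rms(low$data[1, ]) / rms(sine_recording(2)$data[1, ]), 0.10)
  # >= 20 dB down at lo/2 and hi + 10
  half <- bandpass_filter(sine_recording(4), 8, 45)
  expect_lt(20 * log10(rms(half$data[1, ]) /
                         rms(sine_recording(4)$data[1, ])), -20)
  high <- bandpass_filter(sine_recording(55), 8, 45)
  expect_lt(20 * log10(rms(high$data[1, ]) /
                         rms(sine_recording(55)$data[1, ])), -20)
  zero <- bandpass_filter(eeg_recording(matrix(0, 2, 1024), 512,
                                        c("a", "b")), 8, 45)
  expect_true(all(zero$data == 0))
  expect_error(bandpass_filter(sine_recording(10), 45, 8), "lo < hi")
})

test_that("periodogram satisfies Parseval and locates tones", {
  withr::with_seed(42, x <- rnorm(1000))
  sp <- power_spectrum(x, 512)
  expect_lt(abs(sum(sp$power) - mean((x - mean(x))^2)) /
              mean((x - mean(x))^2), 1e-6)

  t <- (0:2047) / 512
  tone <- sin(2 * pi * 10 * t)
  spt <- power_spectrum(tone, 512)
  expect_equal(spt$freq[which.max(spt$power)], 10)

  expect_true(all(power_spectrum(rep(0, 64), 512)$power == 0))
  expect_error(power_spectrum(numeric(1), 512), "at least 2")
})

test_that("white-noise periodogram is flat (no spectral slope)", {
  withr::with_seed(8, x <- rnorm(16384))
  sp <- welch_spectrum(x, 512)
  keep <- sp$freq > 2 & sp$freq < 250
  fit <- stats::lm(log(sp$power[keep]) ~ log(sp$freq[keep]))
  expect_lt(abs(stats::coef(fit)[2]), 0.05)
})

test_that("Morlet transform finds ridges and localises amplitude steps", {
  t <- (0:4095) / 512
  tone <- sin(2 * pi * 10 * t)
  tf <- morlet_cwt(tone, 512, seq(8, 45, by = 0.5))
  mid <- ncol(tf$power) %/% 2
  expect_equal(tf$freq[which.max(tf$power[, mid])], 10)

  step <- sin(2 * pi * 25 * t) * ifelse(t < 4, 1, 2)
  tfs <- morlet_cwt(step, 512, seq(20, 30, by = 0.5))
  row25 <- which(tfs$freq == 25)
  before <- mean(tfs$power[row25, t > 1 & t < 3])
  after <- mean(tfs$power[row25, t > 5 & t < 7])
  expect_gt(after / before, 3)

  expect_true(all(morlet_cwt(rep(0, 512), 512, c(10, 20))$power == 0))
  expect_error(morlet_cwt(tone, 512, c(10, 300)), "rate/2")
})

test_that("wavelet and periodogram agree on the peak frequency", {
  freqs <- seq(8, 45, by = 0.5)
  t <- (0:2047) / 512 # 4 s: periodogram grid contains every 0.5 Hz step
  for (f0 in c(10, 22.5, 30)) {
    tone <- sin(2 * pi * f0 * t)
    sp <- power_spectrum(tone, 512)
    on_grid <- sp$power[match(freqs, sp$freq)]
    tf <- morlet_cwt(tone, 512, freqs)
    expect_identical(freqs[which.max(rowMeans(tf$power))],
                     freqs[which.max(on_grid)])
    expect_identical(freqs[which.max(on_grid)], f0)
  }
})

test_that("relative power follows the dB identities", {
  rest <- matrix(c(1, 2, 4, 8), 2)
  expect_true(all(relative_power_db(rest, rest) == 0))
  expect_equal(relative_power_db(2 * rest, rest),
               matrix(10 * log10(2), 2, 2), tolerance = 1e-6)
  expect_equal(relative_power_db(rest / 10, rest), matrix(-10, 2, 2))
  expect_error(relative_power_db(rest, rest * 0), "strictly positive")
  expect_error(relative_power_db(rest, rest[1, , drop = FALSE]),
               "matching shapes")
})

test_that("band summaries use the exact band edges per electrode", {
  freqs <- seq(8, 45, by = 0.5)
  rel <- matrix(0, nrow = 3, ncol = length(freqs),
                dimnames = list(c("C3", "Cz", "C4"), NULL))
  flat <- band_topography(rel, freqs, "mu")
  expect_equal(flat$power_db, rep(0, 3))
  expect_identical(attr(flat, "edges"), c(8, 13))

  # value placed just outside 13 Hz must not leak into mu
  rel2 <- rel
  rel2[, freqs == 13.5] <- -60
  expect_equal(band_topography(rel2, freqs, "mu")$power_db, rep(0, 3))
  expect_lt(band_topography(rel2, freqs, "low_beta")$power_db[1], 0)

  rel3 <- rel
  rel3["Cz", freqs >= 8 & freqs <= 13] <- -3
  mu <- band_topography(rel3, freqs, "mu")
  expect_identical(mu$electrode[which.min(mu$power_db)], "Cz")

  expect_error(band_topography(rel, freqs + 100, "mu"), "do not cover")
})

test_that("segment_trials yields one grid-aligned trial per usable cycle", {
  sess <- run_closed_loop_session(
    motion_sim_config("pedaling", 2, 21),
    build_pedaling_config(), eeg_sim_config(seed = 12))
  tm <- segment_trials(sess$eeg, sess$segmentation)
  expect_identical(dim(tm)[1], 10L)
  expect_identical(dim(tm)[2], 16L)
  expect_identical(dim(tm)[3], 101L)
  expect_true(all(is.finite(tm)))

  none <- segment_trials(sess$eeg, numeric(0))
  expect_identical(dim(none)[1], 0L)

  # an implausibly long cycle is rejected by the MAD rule
  times <- c(cumsum(c(0, 2 + 0.02 * (1:8))), 20.9)
  tm2 <- suppressWarnings(segment_trials(sess$eeg, times))
  expect_identical(attr(tm2, "dropped_outlier"), 1L)
  expect_identical(dim(tm2)[1], 8L)
})

test_that("grand average normalises every frequency row to 0 dB mean", {
  withr::with_seed(14, {
    base <- matrix(rexp(20 * 50) + 0.5, 20, 50)
    one <- list(freq = 1:20, time = seq(0, 100, length.out = 50),
                power = base)
    class(one) <- "tf_map"
    ga_same <- grand_average(list(one, one, one))
    ga_one <- grand_average(list(one))
    expect_equal(ga_same$power, ga_one$power, tolerance = 1e-12)
    expect_lt(max(abs(rowMeans(ga_same$power))), 1e-12)

    # averaging independent noise maps shrinks pointwise spread ~ 1/sqrt(N)
    mk <- function() {
      m <- one
      m$power <- matrix(rexp(20 * 50) + 0.5, 20, 50)
      m
    }
    sd1 <- sd(grand_average(list(mk()))$power)
    sd16 <- sd(grand_average(replicate(16, mk(), simplify = FALSE))$power)
    expect_lt(sd16, sd1 / 2)
    bad <- mk(); bad$freq <- 2:21
    expect_error(grand_average(list(one, bad)), "same frequency")
  })
})
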