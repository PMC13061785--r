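# Movement-cycle-locked EEG evaluation pipeline: common average reference,
# zero-phase band-pass, cycle-normalised trials, periodogram / Welch / Morlet
# wavelet spectra, relative power in dB versus rest, and band topography
# summaries (mu 8-13, low beta 13-20, high beta 20-30 Hz).

#' EEG recording container
#'
#' @param data Numeric matrix, channels x samples, in uV.
#' @param rate Sampling rate in Hz (> 0).
#' @param labels Character vector of unique electrode names (10-20 system),
#'   one per row of `data`.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, rate, labels) {
  data <- as.matrix(data)
  labels <- as.character(labels)
  if (nrow(data) != length(labels))
    stop("one label per channel required")
  if (anyDuplicated(labels)) stop("electrode labels must be unique")
  if (!is.finite(rate) || rate <= 0) stop("rate must be positive")
  if (!all(is.finite(data))) stop("EEG samples must be finite")
  rownames(data) <- labels
  structure(list(data = data, rate = rate, labels = labels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples at %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel sum is zero at each time point. Idempotent.
#'
#' @param rec An [eeg_recording()] with at least 2 channels.
#' @return The re-referenced `eeg_recording`.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L)
    stop("common average reference requires at least 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data), "-")
  rec
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass (default 4th order) applied forward and backward
#' (`signal::filtfilt`) to every channel, so cycle-locked features are not
#' phase-shifted. The default 8-45 Hz band preserves the mu and beta
#' rhythms while suppressing slow movement artifacts and line-frequency
#' neighbourhood noise.
#'
#' @param rec An [eeg_recording()].
#' @param lo,hi Band edges in Hz, `0 < lo < hi < rate / 2`.
#' @param order Butterworth design order per band edge (default 4).
#' @return The filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, lo = 8, hi = 45, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(lo > 0 && hi > lo && hi < rec$rate / 2))
    stop("need 0 < lo < hi < rate/2")
  bf <- signal::butter(order, c(lo, hi) / (rec$rate / 2), type = "pass")
  for (ch in seq_len(nrow(rec$data)))
    rec$data[ch, ] <- signal::filtfilt(bf, rec$data[ch, ])
  rec
}

#' One-sided periodogram of a single-channel segment
#'
#' FFT periodogram of the demeaned segment, normalised so the total
#' one-sided power equals the time-domain variance (Parseval, population
#' denominator `n`).
#'
#' @param x Numeric vector (>= 2 samples).
#' @param rate Sampling rate in Hz.
#' @return List with `freq` (Hz, from 0 to Nyquist) and `power`.
#' @export
power_spectrum <- function(x, rate) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples for a power spectrum")
  X <- stats::fft(x - mean(x))
  p_full <- Mod(X)^2 / n^2
  nh <- floor(n / 2)
  power <- p_full[1:(nh + 1L)]
  dbl <- if (n %% 2 == 0) seq(2L, nh) else seq(2L, nh + 1L)
  if (length(dbl)) power[dbl] <- 2 * power[dbl]
  list(freq = (0:nh) * rate / n, power = power)
}

#' Welch-averaged power spectrum
#'
#' Mean of Hann-windowed, demeaned periodograms over overlapping segments.
#' Used as the baseline (rest) spectral estimator and for task spectra; the
#' normalisation is consistent across calls so spectral ratios are
#' calibration-free.
#'
#' @param x Numeric vector.
#' @param rate Sampling rate in Hz.
#' @param window_sec Segment length in seconds (default 2, giving 0.5 Hz
#'   resolution at 512 Hz).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `power`, plus `n_segments`.
#' @export
welch_spectrum <- function(x, rate, window_sec = 2, overlap = 0.5) {
  L <- round(window_sec * rate)
  if (length(x) < L) stop("signal shorter than one Welch window")
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1L) / (L - 1L))
  wnorm <- sum(w^2)
  nh <- floor(L / 2)
  acc <- numeric(nh + 1L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    Y <- stats::fft((seg - mean(seg)) * w)
    p <- Mod(Y)^2 / (wnorm * L)
    p1 <- p[1:(nh + 1L)]
    dbl <- if (L %% 2 == 0) seq(2L, nh) else seq(2L, nh + 1L)
    p1[dbl] <- 2 * p1[dbl]
    acc <- acc + p1
  }
  list(freq = (0:nh) * rate / L, power = acc / length(starts),
       n_segments = length(starts))
}

#' Morlet continuous wavelet transform power
#'
#' Complex Morlet wavelet of fixed cycle count (default 6): at analysis
#' frequency f the Gaussian envelope has standard deviation
#' `n_cycles / (2 pi f)` seconds. Power is the squared magnitude of the
#' FFT-based convolution. Wavelets are L1-normalised so a unit-amplitude
#' sinusoid yields the same ridge power at every analysis frequency (the
#' peak over frequency then matches the periodogram peak for stationary
#' tones).
#'
#' @param x Numeric vector of samples.
#' @param rate Sampling rate in Hz.
#' @param freqs Analysis frequencies in Hz, all inside `(0, rate / 2)`.
#' @param n_cycles Wavelet cycle count (default 6).
#' @return A `tf_map`: list with `freq`, `time` (seconds) and `power`
#'   (frequency x time matrix).
#' @export
morlet_cwt <- function(x, rate, freqs, n_cycles = 6) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  if (any(freqs <= 0 | freqs >= rate / 2))
    stop("analysis frequencies must lie in (0, rate/2)")
  power <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sigma <- n_cycles / (2 * pi * f)
    hw <- max(1L, min(ceiling(5 * sigma * rate), n - 1L))
    tt <- (-hw:hw) / rate
    psi <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma^2))
    psi <- 2 * psi / sum(Mod(psi))
    nf <- stats::nextn(n + 2L * hw)
    X <- stats::fft(c(x, rep(0, nf - n)))
    P <- stats::fft(c(psi, rep(0 + 0i, nf - length(psi))))
    conv <- stats::fft(X * P, inverse = TRUE) / nf
    power[i, ] <- Mod(conv[(hw + 1L):(hw + n)])^2
  }
  structure(list(freq = freqs, time = (seq_len(n) - 1L) / rate,
                 power = power),
            class = "tf_map")
}

#' Relative power in dB
#'
#' Elementwise `10 * log10(task / rest)`.
#'
#' @param task_power Numeric vector/matrix of task power.
#' @param rest_power Matching reference power, strictly positive.
#' @return dB values, same shape as the inputs.
#' @export
relative_power_db <- function(task_power, rest_power) {
  if (!identical(dim(task_power), dim(rest_power)) ||
      length(task_power) != length(rest_power))
    stop("task and reference power must have matching shapes")
  if (any(rest_power <= 0))
    stop("reference power must be strictly positive")
  10 * log10(task_power / rest_power)
}

#' Frequency-band definitions used by the band summaries
#'
#' @return Named list of `c(lo, hi)` band edges in Hz: mu 8-13, low beta
#'   13-20, high beta 20-30.
#' @export
eeg_bands <- function() {
  list(mu = c(8, 13), low_beta = c(13, 20), high_beta = c(20, 30))
}

#' Per-electrode band summary (topography values)
#'
#' Mean relative power (dB) within a named band for every electrode; these
#' are the values interpolated into scalp topography maps.
#'
#' @param rel_power_db Matrix electrodes x frequencies of relative power in
#'   dB, with electrode rownames.
#' @param freqs Frequency axis in Hz (one per column).
#' @param band One of `"mu"`, `"low_beta"`, `"high_beta"`.
#' @return A `band_power_summary` data frame (`electrode`, `power_db`) with
#'   attributes `band` and `edges`.
#' @export
band_topography <- function(rel_power_db, freqs,
                            band = c("mu", "low_beta", "high_beta")) {
  band <- match.arg(band)
  rel_power_db <- as.matrix(rel_power_db)
  stopifnot(length(freqs) == ncol(rel_power_db))
  edges <- eeg_bands()[[band]]
  sel <- freqs >= edges[1L] & freqs <= edges[2L]
  if (!any(sel))
    stop(sprintf("spectra do not cover the %s band (%g-%g Hz)",
                 band, edges[1L], edges[2L]))
  out <- data.frame(
    electrode = rownames(rel_power_db) %||% as.character(seq_len(nrow(rel_power_db))),
    power_db = rowMeans(rel_power_db[, sel, drop = FALSE]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(out, class = c("band_power_summary", "data.frame"),
            band = band, edges = edges)
}

#' Extract cycle-locked trials from a recording
#'
#' One trial per movement cycle: each channel's samples between consecutive
#' cycle boundaries are linearly resampled onto a 0-100% cycle grid.
#' Cycles shorter than 2 samples are dropped (counted in attribute
#' `dropped_short`); optionally, cycles whose duration deviates from the
#' median period by more than 3 scaled median absolute deviations are
#' rejected as outliers (`dropped_outlier`).
#'
#' @param rec An [eeg_recording()].
#' @param seg A `cycle_segmentation` (boundary `times` must lie within the
#'   recording span) or a numeric vector of boundary times.
#' @param grid_points Cycle-grid length (default 101: integer percentages).
#' @param reject_outliers Apply the MAD rule (default TRUE).
#' @return A `trial_matrix`: numeric array trials x channels x grid with
#'   dimnames, and attributes `dropped_short`, `dropped_outlier`,
#'   `cycle_percent`.
#' @export
segment_trials <- function(rec, seg, grid_points = 101L,
                           reject_outliers = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  times <- if (inherits(seg, "cycle_segmentation")) seg$times else
    as.numeric(seg)
  n <- ncol(rec$data)
  span <- (n - 1L) / rec$rate
  empty <- function(ds = 0L, do = 0L) {
    a <- array(numeric(0), dim = c(0L, nrow(rec$data), grid_points),
               dimnames = list(NULL, rec$labels, NULL))
    structure(a, class = "trial_matrix", dropped_short = ds,
              dropped_outlier = do,
              cycle_percent = seq(0, 100, length.out = grid_points))
  }
  if (length(times) < 2L) return(empty())
  if (min(times) < 0 || max(times) > span + 1 / rec$rate)
    stop("cycle boundaries must lie within the recording span")
  periods <- diff(times)
  keep <- rep(TRUE, length(periods))
  dropped_outlier <- 0L
  if (reject_outliers && length(periods) >= 3L) {
    md <- stats::median(periods)
    s <- stats::mad(periods)
    if (s > 0) {
      keep <- abs(periods - md) <= 3 * s
      dropped_outlier <- sum(!keep)
    }
  }
  idx0 <- pmax(1L, floor(times[-length(times)] * rec$rate) + 1L)
  idx1 <- pmin(n, floor(times[-1L] * rec$rate) + 1L)
  short <- (idx1 - idx0 + 1L) < 2L
  dropped_short <- sum(short & keep)
  keep <- keep & !short
  if (!any(keep)) return(empty(dropped_short, dropped_outlier))
  kept <- which(keep)
  out <- array(NA_real_,
               dim = c(length(kept), nrow(rec$data), grid_points),
               dimnames = list(NULL, rec$labels, NULL))
  for (j in seq_along(kept)) {
    i <- kept[j]
    sl <- idx0[i]:idx1[i]
    for (ch in seq_len(nrow(rec$data)))
      out[j, ch, ] <- resample_cycle(rec$data[ch, sl], grid_points)
  }
  if (dropped_short + dropped_outlier > 0L)
    warning(sprintf("dropped %d short and %d outlier cycle(s)",
                    dropped_short, dropped_outlier))
  structure(out, class = "trial_matrix", dropped_short = dropped_short,
            dropped_outlier = dropped_outlier,
            cycle_percent = seq(0, 100, length.out = grid_points))
}

#' Per-cycle Morlet time-frequency maps on the cycle grid
#'
#' Computes the wavelet power of one channel over the whole recording, then
#' slices it at the cycle boundaries and resamples each frequency row onto
#' the 0-100% cycle grid, yielding one `tf_map` per cycle (all sharing the
#' same grids) ready for [grand_average()].
#'
#' @param rec An [eeg_recording()] (typically already referenced and
#'   band-passed).
#' @param channel Electrode label (e.g. `"Cz"`).
#' @param seg A `cycle_segmentation` or numeric boundary times.
#' @param freqs Analysis frequencies in Hz (default 8-45 Hz in 0.5 Hz
#'   steps).
#' @param grid_points Cycle-grid length (default 101).
#' @param n_cycles Morlet cycle count (default 6).
#' @return List of `tf_map`s, one per cycle (frequency x cycle-percent).
#' @export
cycle_tf_maps <- function(rec, channel, seg,
                          freqs = seq(8, 45, by = 0.5),
                          grid_points = 101L, n_cycles = 6) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!channel %in% rec$labels)
    stop(sprintf("channel '%s' not present in the montage", channel))
  times <- if (inherits(seg, "cycle_segmentation")) seg$times else
    as.numeric(seg)
  if (length(times) < 2L) return(list())
  tf <- morlet_cwt(rec$data[channel, ], rec$rate, freqs,
                   n_cycles = n_cycles)
  n <- ncol(rec$data)
  idx0 <- pmax(1L, floor(times[-length(times)] * rec$rate) + 1L)
  idx1 <- pmin(n, floor(times[-1L] * rec$rate) + 1L)
  pct <- seq(0, 100, length.out = grid_points)
  maps <- vector("list", length(idx0))
  for (i in seq_along(idx0)) {
    if (idx1[i] - idx0[i] + 1L < 2L) next
    sl <- idx0[i]:idx1[i]
    p <- t(apply(tf$power[, sl, drop = FALSE], 1L, resample_cycle,
                 n_points = grid_points))
    maps[[i]] <- structure(list(freq = freqs, time = pct, power = p),
                           class = "tf_map")
  }
  maps[!vapply(maps, is.null, TRUE)]
}

#' Grand average of per-trial time-frequency maps
#'
#' Averages the power maps elementwise across trials, then expresses each
#' frequency row in dB relative to its mean power over the movement cycle
#' (geometric mean across cycle positions), so every frequency row averages
#' to exactly 0 dB.
#'
#' @param maps List of `tf_map`s sharing identical frequency and time grids
#'   (e.g. from [cycle_tf_maps()]).
#' @return A `tf_map` whose `power` holds dB values (attribute
#'   `units = "dB"`).
#' @export
grand_average <- function(maps) {
  if (!is.list(maps) || length(maps) < 1L)
    stop("need at least one trial map")
  f0 <- maps[[1L]]$freq; t0 <- maps[[1L]]$time
  for (m in maps)
    if (!isTRUE(all.equal(m$freq, f0)) || !isTRUE(all.equal(m$time, t0)))
      stop("all trial maps must share the same frequency and time grids")
  P <- Reduce(`+`, lapply(maps, `[[`, "power")) / length(maps)
  if (any(P <= 0)) stop("trial power must be strictly positive to average in dB")
  db <- 10 * log10(P)
  db <- db - rowMeans(db)
  structure(list(freq = f0, time = t0, power = db),
            class = "tf_map", units = "dB", reference = "cycle_mean")
}

#' Full relative-power analysis of a movement session against rest
#'
#' The evaluation pipeline applied to a task and a rest recording sharing
#' montage and rate: common average reference, zero-phase band-pass
#' (`lo`-`hi` Hz), Welch spectra of the movement span (first to last cycle
#' boundary) and of the rest recording, per-electrode relative power in dB,
#' the three band topography summaries, and (optionally) the grand-average
#' Morlet map of one channel on the 0-100% cycle grid.
#'
#' @param task_rec,rest_rec [eeg_recording()]s with identical labels and
#'   rate.
#' @param seg A `cycle_segmentation` (or numeric boundary times) aligned
#'   with `task_rec`.
#' @param lo,hi Band-pass edges in Hz (defaults 8 and 45).
#' @param window_sec Welch window length in seconds (default 2).
#' @param tf_channel Electrode label for the time-frequency map, or `NULL`
#'   to skip it (default `"Cz"`).
#' @param grid_points Cycle-grid length for the map (default 101).
#' @return List with `freqs`, `rel_power_db` (electrodes x frequencies),
#'   `band_summaries` (named list of [band_topography()] results), `tf`
#'   (grand-average `tf_map` or `NULL`) and `n_cycles`.
#' @export
erd_analysis <- function(task_rec, rest_rec, seg, lo = 8, hi = 45,
                         window_sec = 2, tf_channel = "Cz",
                         grid_points = 101L) {
  stopifnot(inherits(task_rec, "eeg_recording"),
            inherits(rest_rec, "eeg_recording"))
  if (!identical(task_rec$labels, rest_rec$labels) ||
      task_rec$rate != rest_rec$rate)
    stop("task and rest recordings must share montage and rate")
  times <- if (inherits(seg, "cycle_segmentation")) seg$times else
    as.numeric(seg)
  task <- bandpass_filter(common_average_reference(task_rec), lo, hi)
  rest <- bandpass_filter(common_average_reference(rest_rec), lo, hi)
  n <- ncol(task$data)
  if (length(times) >= 2L) {
    i0 <- max(1L, floor(times[1L] * task$rate) + 1L)
    i1 <- min(n, floor(times[length(times)] * task$rate) + 1L)
  } else {
    i0 <- 1L; i1 <- n
  }
  spec_of <- function(x) welch_spectrum(x, task$rate, window_sec)
  ref <- spec_of(rest$data[1L, ])
  sel <- ref$freq >= lo & ref$freq <= hi
  freqs <- ref$freq[sel]
  nch <- nrow(task$data)
  task_p <- matrix(NA_real_, nch, sum(sel),
                   dimnames = list(task$labels, NULL))
  rest_p <- task_p
  for (ch in seq_len(nch)) {
    task_p[ch, ] <- spec_of(task$data[ch, i0:i1])$power[sel]
    rest_p[ch, ] <- spec_of(rest$data[ch, ])$power[sel]
  }
  rel <- relative_power_db(task_p, rest_p)
  summaries <- lapply(stats::setNames(nm = names(eeg_bands())),
                      function(b) band_topography(rel, freqs, b))
  tf <- NULL
  if (!is.null(tf_channel) && length(times) >= 2L) {
    maps <- cycle_tf_maps(task, tf_channel, times,
                          freqs = seq(lo, hi, by = 0.5),
                          grid_points = grid_points)
    if (length(maps)) tf <- grand_average(maps)
  }
  list(freqs = freqs, rel_power_db = rel, band_summaries = summaries,
       tf = tf, n_cycles = max(0L, length(times) - 1L))
}
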