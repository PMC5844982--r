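# Conventional trunk-acceleration gait features computable without a body
# model: variability, regularity, harmonic content, spectral shape and
# local dynamic stability.

#' Welch power spectral density
#'
#' Hamming-windowed segments of `segment_s` seconds with 50% overlap,
#' averaged modified periodograms.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param segment_s segment length (s).
#' @param overlap fractional overlap between segments.
#' @return List with `freq` and `power`.
#' @export
welch_psd <- function(x, fs, segment_s = 5, overlap = 0.5) {
  nseg <- min(length(x), round(segment_s * fs))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  u <- sum(w^2) / nseg
  half <- seq_len(floor(nseg / 2) + 1)
  acc <- numeric(length(half))
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + (Mod(fft(seg))^2 / (nseg * u))[half]
  }
  list(freq = (half - 1) * fs / nseg, power = acc / length(starts))
}

magnitude_signal <- function(m) sqrt(rowSums(m^2))

#' Acceleration standard deviations
#'
#' SD per axis plus the SD of the Euclidean-norm (vector magnitude) signal.
#'
#' @param epoch an [accel_epoch()].
#' @return Named numeric vector `sd_AP`, `sd_ML`, `sd_V`, `sd_mag`.
#' @export
basic_stats <- function(epoch) {
  m <- epoch_matrix(epoch)
  c(sd_AP = sd(m[, "AP"]), sd_ML = sd(m[, "ML"]), sd_V = sd(m[, "V"]),
    sd_mag = sd(magnitude_signal(m)))
}

unbiased_autocorr <- function(x, lag) {
  n <- length(x)
  if (lag >= n - 1) return(NA_real_)
  x <- x - mean(x)
  sum(x[1:(n - lag)] * x[(1 + lag):n]) / ((n - lag) * stats::var(x) * (n - 1) / n)
}

#' Stride regularity and stride-timing statistics
#'
#' Regularity is the unbiased autocorrelation coefficient of each direction
#' (and the vector magnitude) at the stride lag (two steps). Stride times
#' are read from alternate cycle boundaries.
#'
#' @param epoch an [accel_epoch()].
#' @param cycles a `step_cycles` object.
#' @param min_cycles minimum number of valid cycles required.
#' @return Named vector: per-direction regularity, `stride_time`,
#'   `stride_freq`, `stride_time_var`, `stride_freq_var`.
#' @export
stride_regularity <- function(epoch, cycles, min_cycles = 10L) {
  if (sum(cycles$valid) < min_cycles) {
    stop_data("fewer than ", min_cycles, " valid cycles")
  }
  fs <- epoch_fs(epoch)
  m <- epoch_matrix(epoch)
  b <- cycles$boundaries
  strides <- (b[seq(3, length(b), by = 2)] -
                b[seq(1, length(b) - 2, by = 2)]) / fs
  stride_time <- mean(strides)
  lag <- round(stride_time * fs)
  vals <- c(vapply(AXES, function(a) unbiased_autocorr(m[, a], lag),
                   numeric(1)),
            mag = unbiased_autocorr(magnitude_signal(m), lag))
  names(vals) <- paste0("regularity_", c(AXES, "mag"))
  c(vals, stride_time = stride_time, stride_freq = 1 / stride_time,
    stride_time_var = sd(strides), stride_freq_var = sd(1 / strides))
}

# summed amplitude spectrum within +/- half_bw of each target frequency
band_amplitude <- function(x, fs, targets, half_bw = 0.15) {
  n <- length(x)
  amp <- Mod(fft(x - mean(x)))[seq_len(floor(n / 2) + 1)] * 2 / n
  freq <- (seq_along(amp) - 1) * fs / n
  vapply(targets, function(f0) {
    sum(amp[freq >= f0 - half_bw & freq <= f0 + half_bw])
  }, numeric(1))
}

band_power <- function(x, fs, targets, half_bw = 0.15) {
  pg <- periodogram(x - mean(x), fs)
  vapply(targets, function(f0) {
    sum(pg$power[pg$freq >= f0 - half_bw & pg$freq <= f0 + half_bw])
  }, numeric(1))
}

#' Harmonic ratio per direction
#'
#' Amplitudes of the first 20 harmonics of the stride frequency; the ratio
#' is even-to-odd harmonic sums for AP and V (step-periodic components
#' dominate) and odd-to-even for ML (stride-periodic components dominate).
#'
#' @param epoch an [accel_epoch()].
#' @param stride_freq stride frequency (Hz).
#' @param n_harmonics number of stride harmonics (default 20).
#' @return Named vector `hr_AP`, `hr_ML`, `hr_V`.
#' @export
harmonic_ratio <- function(epoch, stride_freq, n_harmonics = 20) {
  fs <- epoch_fs(epoch)
  m <- epoch_matrix(epoch)
  targets <- stride_freq * seq_len(n_harmonics)
  out <- vapply(AXES, function(a) {
    amp <- band_amplitude(m[, a], fs, targets)
    ev <- sum(amp[seq(2, n_harmonics, by = 2)])
    od <- sum(amp[seq(1, n_harmonics, by = 2)])
    floor_ <- 1e-10 * max(ev + od, .Machine$double.eps)
    if (a == "ML") od / max(ev, floor_) else ev / max(od, floor_)
  }, numeric(1))
  names(out) <- paste0("hr_", AXES)
  out
}

#' Index of harmonicity per direction
#'
#' Power at the fundamental divided by the cumulative power of the
#' fundamental plus the first five higher harmonics; lies in \[0, 1\]. The
#' fundamental is the stride frequency for ML and the step frequency for AP
#' and V.
#'
#' @param epoch an [accel_epoch()].
#' @param stride_freq stride frequency (Hz).
#' @return Named vector `ih_AP`, `ih_ML`, `ih_V`.
#' @export
index_of_harmonicity <- function(epoch, stride_freq) {
  fs <- epoch_fs(epoch)
  m <- epoch_matrix(epoch)
  out <- vapply(AXES, function(a) {
    f0 <- if (a == "ML") stride_freq else 2 * stride_freq
    pw <- band_power(m[, a], fs, f0 * (1:6))
    tot <- sum(pw)
    if (tot <= 0) return(0)
    pw[1] / tot
  }, numeric(1))
  names(out) <- paste0("ih_", AXES)
  out
}

#' Spectral shape features per direction
#'
#' From a Welch periodogram (5-s segments, 50% overlap): dominant frequency
#' (peak in `dom_band`), its normalized amplitude (peak power over total
#' 0.5-10 Hz power), the full width at half the peak, the log-log spectral
#' slope over 0.5-10 Hz, and the band holding the central 98% of 0-10 Hz
#' power.
#'
#' @param epoch an [accel_epoch()].
#' @param dom_band search band (Hz) for the dominant peak.
#' @return Named vector of `dom_freq_*`, `amp_*`, `width_*`, `slope_*`,
#'   `range_*` per axis.
#' @export
spectral_features <- function(epoch, dom_band = c(0.5, 3)) {
  fs <- epoch_fs(epoch)
  m <- epoch_matrix(epoch)
  out <- c()
  for (a in AXES) {
    pg <- welch_psd(m[, a], fs)
    sel_all <- pg$freq > 0 & pg$freq <= 10
    sel_dom <- pg$freq >= dom_band[1] & pg$freq <= dom_band[2]
    fd <- pg$freq[sel_dom][which.max(pg$power[sel_dom])]
    pk <- max(pg$power[sel_dom])
    amp <- pk / sum(pg$power[pg$freq >= 0.5 & pg$freq <= 10])
    # full width at half maximum around the dominant peak
    half <- pk / 2
    ip <- which(pg$freq == fd)
    lo <- ip; while (lo > 1 && pg$power[lo] > half) lo <- lo - 1
    hi <- ip; while (hi < length(pg$power) && pg$power[hi] > half) hi <- hi + 1
    width <- pg$freq[hi] - pg$freq[lo]
    sel_fit <- pg$freq >= 0.5 & pg$freq <= 10 & pg$power > 0
    slope <- coef(lm(log(pg$power[sel_fit]) ~ log(pg$freq[sel_fit])))[2]
    cum <- cumsum(pg$power[sel_all]) / sum(pg$power[sel_all])
    fr <- pg$freq[sel_all]
    rng <- fr[min(which(cum >= 0.99))] - fr[max(which(cum <= 0.01), 1)]
    v <- c(fd, amp, width, slope, rng)
    names(v) <- paste0(c("dom_freq_", "amp_", "width_", "slope_", "range_"), a)
    out <- c(out, v)
  }
  out
}

#' Low-frequency percentage
#'
#' Percent of the 0-10 Hz spectral power lying below `cutoff` Hz, per axis
#' and for the vector magnitude.
#'
#' @param epoch an [accel_epoch()].
#' @param cutoff low-frequency cutoff (Hz).
#' @return Named vector `lfp_AP`, `lfp_ML`, `lfp_V`, `lfp_mag` (percent).
#' @export
low_freq_percentage <- function(epoch, cutoff = 0.7) {
  fs <- epoch_fs(epoch)
  m <- epoch_matrix(epoch)
  sigs <- cbind(m, mag = magnitude_signal(m))
  out <- vapply(seq_len(4), function(i) {
    pg <- welch_psd(sigs[, i], fs)
    sel <- pg$freq > 0 & pg$freq <= 10
    100 * sum(pg$power[sel & pg$freq < cutoff]) / sum(pg$power[sel])
  }, numeric(1))
  names(out) <- paste0("lfp_", c(AXES, "mag"))
  out
}
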