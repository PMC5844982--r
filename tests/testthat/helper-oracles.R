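# Independent oracles and fixture builders shared by the tests.

# Brute-force sample-entropy match counting: a literal double loop over
# ordered pairs (i != j, |i - j| > theiler) with explicit max-norm
# distances. Written independently of the package kernel on purpose.
brute_match_counts <- function(X, Y, idx, r, theiler = 0L) {
  n_pairs <- 0L
  hits_x <- 0L
  hits_y <- 0L
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (a == b) next
      if (abs(idx[a] - idx[b]) <= theiler) next
      n_pairs <- n_pairs + 1L
      dx <- 0
      for (c in seq_len(ncol(X))) {
        dd <- abs(X[a, c] - X[b, c])
        if (dd > dx) dx <- dd
      }
      if (dx <= r) hits_x <- hits_x + 1L
      dy <- 0
      for (c in seq_len(ncol(Y))) {
        dd <- abs(Y[a, c] - Y[b, c])
        if (dd > dy) dy <- dd
      }
      if (dy <= r) hits_y <- hits_y + 1L
    }
  }
  list(n_x = hits_x / n_pairs, n_y = hits_y / n_pairs,
       pairs = n_pairs)
}

# Brute-force conventional sample entropy ln(n_x / n_y) for a tri-axial
# series via the delay-space pair, whole index set.
brute_sampen <- function(series, lag, r, theiler = 0L) {
  n <- nrow(series)
  tn <- n - 2L * lag
  j <- seq_len(tn)
  Y <- cbind(series[j, , drop = FALSE], series[j + lag, , drop = FALSE],
             series[j + 2L * lag, , drop = FALSE])
  X <- Y[, 1:6, drop = FALSE]
  cnt <- brute_match_counts(X, Y, j, r, theiler)
  if (cnt$n_y == 0) return(NA_real_)
  log(cnt$n_x / cnt$n_y)
}

# Tri-axial tone epoch: identical frequency on all axes with distinct
# phases/amplitudes so every channel has extrema.
tone_epoch <- function(freq = 2, fs = 100, duration = 10, amp = c(1, 0.8, 1.2),
                       phase = c(0, 0.7, 1.4), noise = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  m <- sapply(1:3, function(i) {
    amp[i] * sin(2 * pi * freq * t + phase[i]) +
      if (noise > 0) rnorm(length(t), 0, noise) else 0
  })
  colnames(m) <- c("AP", "ML", "V")
  accel_epoch(m, fs = fs)
}

noise_epoch <- function(fs = 100, duration = 10, sd = 1) {
  m <- matrix(rnorm(round(duration * fs) * 3, 0, sd), ncol = 3,
              dimnames = list(NULL, c("AP", "ML", "V")))
  accel_epoch(m, fs = fs)
}

# Short-duration generator settings used throughout the tests to keep the
# suite fast; the waveform/noise structure is the generator default.
quick_params <- function(duration = 8, ...) {
  gait_sim_params(duration = duration, ...)
}

quick_entropy_cfg <- function(scales = 1:3, q_grid = c(-1, 0, 1),
                              n_dirs = 8, max_sift = 8, max_lag = 50L,
                              bins = 16L, ...) {
  # AMI bins scale with epoch length: 32 bins are too sparse for the short
  # validation epochs and make the selected lag noise-sensitive
  entropy_config(scales = scales, q_grid = q_grid, n_dirs = n_dirs,
                 max_sift = max_sift, max_lag = max_lag, bins = bins, ...)
}

# Cohort feature fixture for the prediction tests: two Gaussian clouds with
# `n_inform` informative columns separated by `delta` SDs plus pure-noise
# columns, wrapped in a cohort_table with matched pairs.
toy_cohort <- function(n_pairs = 20, n_inform = 2, n_noise = 8,
                       delta = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_pairs
  label <- rep(c(1L, 0L), n_pairs)
  inf <- matrix(rnorm(n * n_inform), n) + outer(label, rep(delta, n_inform))
  noi <- matrix(rnorm(n * n_noise), n)
  X <- cbind(inf, noi)
  colnames(X) <- c(paste0("inform", seq_len(n_inform)),
                   paste0("noise", seq_len(n_noise)))
  subjects <- data.frame(id = sprintf("S%02d", seq_len(n)), label = label,
                         pair_id = rep(seq_len(n_pairs), each = 2))
  cohort_table(subjects, X)
}
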