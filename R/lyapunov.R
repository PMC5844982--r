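# Largest Lyapunov exponent estimators (Rosenstein and Wolf variants) for
# local dynamic stability of gait.

embed_univariate <- function(x, dim, lag) {
  n <- length(x) - (dim - 1) * lag
  if (n < 10) stop_data("series too short for embedding")
  sapply(seq_len(dim), function(k) x[(1 + (k - 1) * lag):(n + (k - 1) * lag)])
}

mean_period_samples <- function(x, fs) {
  pg <- periodogram(x - mean(x), fs)
  sel <- pg$freq > 0
  fmean <- sum(pg$freq[sel] * pg$power[sel]) / sum(pg$power[sel])
  max(1L, round(fs / fmean))
}

#' Largest Lyapunov exponent, Rosenstein's method
#'
#' Delay-embeds the series, tracks the divergence of each point from its
#' nearest neighbor (with temporal separation beyond the mean period), and
#' fits the slope of the mean log divergence over `fit_range` (in units of
#' `stride_s`).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param dim embedding dimension.
#' @param lag embedding lag in samples (`NULL`: AMI flattening rule on `x`).
#' @param stride_s reference stride time (s) defining the fit range.
#' @param fit_range divergence-curve fit range in strides.
#' @return List with `lambda` (per second), `lambda_per_stride`, and the
#'   divergence curve.
#' @export
lyapunov_rosenstein <- function(x, fs, dim = 5, lag = NULL, stride_s = 1,
                                fit_range = c(0, 0.5)) {
  if (is.null(lag)) {
    ami <- ami_univariate(x, max_lag = min(100L, floor(length(x) / 3)))
    lag <- select_lag(ami)
  }
  E <- embed_univariate(x, dim, lag)
  n <- nrow(E)
  sep <- mean_period_samples(x, fs)
  k_max <- max(2L, round(fit_range[2] * stride_s * fs))
  D2 <- as.matrix(stats::dist(E))^2
  diag(D2) <- Inf
  for (off in seq_len(min(sep, n - 1))) {
    idx <- seq_len(n - off)
    D2[cbind(idx, idx + off)] <- Inf
    D2[cbind(idx + off, idx)] <- Inf
  }
  usable <- seq_len(n - k_max)
  if (length(usable) < 10) stop_data("insufficient neighbors for divergence")
  nb <- apply(D2[usable, usable, drop = FALSE], 1, which.min)
  d0 <- sqrt(D2[cbind(usable, usable[nb])])
  keep <- is.finite(d0) & d0 > 0
  if (sum(keep) < 10) stop_data("insufficient neighbors for divergence")
  i0 <- usable[keep]; j0 <- usable[nb][keep]
  logd <- vapply(0:k_max, function(k) {
    d <- sqrt(rowSums((E[i0 + k, , drop = FALSE] -
                         E[j0 + k, , drop = FALSE])^2))
    mean(log(d[d > 0]))
  }, numeric(1))
  tt <- (0:k_max) / fs
  # k = 0 reflects the initial neighbor distance (noise floor), not
  # divergence; the fit starts one step in
  fit_sel <- tt >= fit_range[1] * stride_s & tt <= fit_range[2] * stride_s
  fit_sel[1] <- FALSE
  lambda <- unname(coef(lm(logd[fit_sel] ~ tt[fit_sel]))[2])
  list(lambda = lambda, lambda_per_stride = lambda * stride_s,
       time = tt, log_divergence = logd)
}

# AMI curve of a single channel (same estimator as the tri-axial version)
ami_univariate <- function(x, max_lag = 100L, bins = 32L) {
  average_mutual_information(cbind(AP = x, ML = x, V = x),
                             max_lag = max_lag, bins = bins)
}

#' Largest Lyapunov exponent, Wolf's trajectory-following method
#'
#' Follows a fiducial trajectory, accumulating log stretch rates between the
#' trajectory and a neighbor, replacing the neighbor (closest admissible
#' point) whenever the separation exceeds `scale_max` times the attractor
#' size.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param dim embedding dimension.
#' @param lag embedding lag in samples (`NULL`: AMI flattening rule).
#' @param evolve evolution interval in samples.
#' @param scale_max replacement threshold as a fraction of attractor size.
#' @param stride_s reference stride time (s).
#' @return List with `lambda` (per second) and `lambda_per_stride`.
#' @export
lyapunov_wolf <- function(x, fs, dim = 5, lag = NULL, evolve = NULL,
                          scale_max = 0.1, stride_s = 1) {
  if (is.null(lag)) {
    ami <- ami_univariate(x, max_lag = min(100L, floor(length(x) / 3)))
    lag <- select_lag(ami)
  }
  if (is.null(evolve)) evolve <- max(2L, round(0.05 * fs))
  E <- embed_univariate(x, dim, lag)
  n <- nrow(E)
  sep <- mean_period_samples(x, fs)
  size <- sqrt(sum(apply(E, 2, stats::var)))
  dmax <- scale_max * size
  find_neighbor <- function(i, ref) {
    d <- sqrt(rowSums((E - matrix(ref, n, dim, byrow = TRUE))^2))
    d[abs(seq_len(n) - i) <= sep] <- Inf
    d[d == 0] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j])) NULL else j
  }
  i <- 1L
  j <- find_neighbor(i, E[i, ])
  if (is.null(j)) stop_data("insufficient neighbors for Wolf estimator")
  total <- 0
  steps <- 0L
  while (i + evolve <= n && j + evolve <= n) {
    d0 <- sqrt(sum((E[i, ] - E[j, ])^2))
    i2 <- i + evolve; j2 <- j + evolve
    d1 <- sqrt(sum((E[i2, ] - E[j2, ])^2))
    if (d0 > 0 && d1 > 0) {
      total <- total + log(d1 / d0)
      steps <- steps + 1L
    }
    i <- i2
    if (d1 > dmax || d1 == 0) {
      j <- find_neighbor(i, E[i, ])
      if (is.null(j)) break
    } else {
      j <- j2
    }
  }
  if (steps == 0) stop_data("insufficient neighbors for Wolf estimator")
  lambda <- total / (steps * evolve / fs)
  list(lambda = lambda, lambda_per_stride = lambda * stride_s)
}

#' Lyapunov exponents of an epoch, per direction
#'
#' @param epoch an [accel_epoch()].
#' @param method `"rosenstein"` or `"wolf"`.
#' @param per_stride multiply exponents by the mean stride time.
#' @param stride_s mean stride time (s).
#' @param dim,lag embedding settings (see the individual estimators).
#' @return Named vector over AP, ML, V and vector magnitude.
#' @export
lyapunov <- function(epoch, method = c("rosenstein", "wolf"),
                     per_stride = FALSE, stride_s = 1, dim = 5, lag = NULL) {
  method <- match.arg(method)
  fs <- epoch_fs(epoch)
  m <- epoch_matrix(epoch)
  sigs <- cbind(m, mag = magnitude_signal(m))
  out <- vapply(seq_len(4), function(i) {
    est <- if (method == "rosenstein") {
      lyapunov_rosenstein(sigs[, i], fs, dim = dim, lag = lag,
                          stride_s = stride_s)
    } else {
      lyapunov_wolf(sigs[, i], fs, dim = dim, lag = lag,
                    stride_s = stride_s)
    }
    if (per_stride) est$lambda_per_stride else est$lambda
  }, numeric(1))
  suffix <- if (per_stride) "_stride" else ""
  names(out) <- paste0("lyap_", substr(method, 1, 1), suffix, "_",
                       c(AXES, "mag"))
  out
}

#' Full conventional gait-feature vector of one epoch
#'
#' Bundles [basic_stats()], [stride_regularity()], [harmonic_ratio()],
#' [index_of_harmonicity()], [spectral_features()], [low_freq_percentage()]
#' and the four [lyapunov()] variants into one named vector.
#'
#' @param epoch an [accel_epoch()].
#' @param cycles a `step_cycles` object; computed from the epoch when `NULL`.
#' @param include_lyapunov set `FALSE` to skip the (slow) Lyapunov block.
#' @return Named numeric vector.
#' @export
gait_feature_vector <- function(epoch, cycles = NULL,
                                include_lyapunov = TRUE) {
  if (is.null(cycles)) {
    vel <- estimate_velocity(epoch)
    cycles <- detect_step_cycles(vel)
  }
  reg <- stride_regularity(epoch, cycles)
  stride_freq <- unname(reg["stride_freq"])
  stride_s <- unname(reg["stride_time"])
  out <- c(basic_stats(epoch), reg,
           harmonic_ratio(epoch, stride_freq),
           index_of_harmonicity(epoch, stride_freq),
           spectral_features(epoch),
           low_freq_percentage(epoch))
  if (include_lyapunov) {
    out <- c(out,
             lyapunov(epoch, "rosenstein", stride_s = stride_s),
             lyapunov(epoch, "wolf", stride_s = stride_s),
             lyapunov(epoch, "rosenstein", per_stride = TRUE,
                      stride_s = stride_s),
             lyapunov(epoch, "wolf", per_stride = TRUE,
                      stride_s = stride_s))
  }
  out
}
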