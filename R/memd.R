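# Multivariate empirical mode decomposition (wrapper around the C++ sifter)
# and the coarse-grained dynamics built from it.

#' Low-discrepancy direction vectors on the unit sphere
#'
#' Hammersley points in the unit cube, pushed through the inverse-normal map
#' and normalized, give a low-discrepancy cover of the unit `(d-1)`-sphere
#' used for the MEMD projections.
#'
#' @param n number of directions.
#' @param d ambient dimension (number of channels).
#' @return n x d matrix of unit vectors.
#' @export
hammersley_directions <- function(n, d) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43)
  if (d - 1 > length(primes)) stop_config("too many channels for direction set")
  radical_inverse <- function(i, base) {
    out <- 0; f <- 1 / base
    while (i > 0) {
      out <- out + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    out
  }
  u <- cbind((seq_len(n) - 0.5) / n,
             vapply(seq_len(max(d - 1, 1)), function(k) {
               vapply(seq_len(n), radical_inverse, numeric(1),
                      base = primes[k])
             }, numeric(n))[, seq_len(d - 1), drop = FALSE])
  z <- qnorm(pmin(pmax(u[, seq_len(d), drop = FALSE], 1e-12), 1 - 1e-12))
  z / sqrt(rowSums(z^2))
}

count_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(0L)
  mid <- x[2:(n - 1)]
  sum(mid > x[1:(n - 2)] & mid > x[3:n]) +
    sum(mid < x[1:(n - 2)] & mid < x[3:n])
}

#' Multivariate empirical mode decomposition
#'
#' Decomposes a d-channel signal into intrinsic mode functions (high to low
#' frequency) plus a residual by directional-projection sifting: the signal
#' is projected onto low-discrepancy direction vectors, cubic-spline
#' envelopes are passed through the signal at the projected-extrema times
#' (with mirror extension of two extrema at each end), and the mean envelope
#' over directions is subtracted until the envelope-to-candidate norm ratio
#' stays below `tol` on two consecutive sifts (or `max_sift` is reached).
#' Extraction repeats on the remainder until fewer than 3 extrema survive in
#' every projection.
#'
#' @param signal numeric T x d matrix, `d >= 2`.
#' @param n_dirs number of projection directions.
#' @param max_sift sift cap per IMF.
#' @param tol envelope-ratio stopping tolerance.
#' @param max_imf optional cap on the number of IMFs extracted.
#' @param fs sampling rate (Hz), carried for frequency bookkeeping.
#' @return An `imf_decomposition` with `imfs` (list of T x d matrices),
#'   `residual`, `M`, and sifting metadata.
#' @export
memd <- function(signal, n_dirs = 64, max_sift = 15, tol = 0.075,
                 max_imf = Inf, fs = NULL) {
  x <- as.matrix(signal)
  if (ncol(x) < 2) stop_config("MEMD needs at least 2 channels")
  check_finite(x, "MEMD input")
  if (any(apply(x, 2, count_extrema) < 4)) {
    stop_data("degenerate MEMD input: a channel has fewer than 4 extrema")
  }
  dirs <- hammersley_directions(n_dirs, ncol(x))
  cap <- if (is.finite(max_imf)) as.integer(max_imf) else
    as.integer(ceiling(log2(nrow(x))) + 4L)
  res <- .memd_sift_cpp(x, dirs, cap, as.integer(max_sift), tol)
  new_imf_decomposition(res$imfs, res$residual, sifts = res$sifts,
                        n_dirs = n_dirs, fs = fs)
}

#' Zero-crossing frequency of a signal (Hz)
#'
#' Sign changes per unit time divided by two: the oscillation frequency a
#' zero-mean mode exhibits.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @return Frequency in Hz.
#' @export
zero_crossing_freq <- function(x, fs) {
  n <- length(x)
  zc <- sum(x[-n] * x[-1] < 0)
  zc / (2 * (n - 1) / fs)
}

#' Coarse-grained dynamics at scale k
#'
#' The scale-k coarse-grained series is the sum of IMFs k..M plus the
#' residual; scale 1 returns the original signal (to reconstruction
#' tolerance) and larger k its progressively low-pass-filtered versions.
#' Scales beyond the number of extracted IMFs are flagged missing rather
#' than filled.
#'
#' @param dec an `imf_decomposition` from [memd()].
#' @param k scale (`>= 1`).
#' @return List with `series` (T x d matrix or `NULL`), `scale`, `missing`.
#' @export
coarse_grain <- function(dec, k) {
  if (k < 1) stop_config("scale k must be >= 1")
  if (k > dec$M) {
    return(list(series = NULL, scale = k, missing = TRUE))
  }
  s <- dec$residual
  for (i in k:dec$M) s <- s + dec$imfs[[i]]
  list(series = s, scale = k, missing = FALSE)
}

#' Remove slow trends from a multichannel signal by MEMD
#'
#' Subtracts, per channel, the MEMD residual and every IMF whose
#' zero-crossing frequency on that channel is below `cutoff_hz`. Intra-step
#' variation is preserved while integration drift and inter-stride trends
#' are removed.
#'
#' @param signal numeric T x d matrix.
#' @param fs sampling rate (Hz).
#' @param cutoff_hz zero-crossing-frequency cutoff (Hz).
#' @param n_dirs,max_sift,tol MEMD settings, see [memd()].
#' @param early_stop stop extracting once a mode is below the cutoff on
#'   every channel (the not-yet-extracted remainder is slower still and is
#'   removed wholesale); `FALSE` runs the full decomposition first.
#' @return List with `detrended` (T x d) and `removed` (per-channel removed
#'   IMF indices, `Inf` marking the residual trend).
#' @export
detrend_memd <- function(signal, fs, cutoff_hz = 0.5, n_dirs = 64,
                         max_sift = 15, tol = 0.075, early_stop = TRUE) {
  x <- as.matrix(signal)
  if (ncol(x) < 2) stop_config("MEMD needs at least 2 channels")
  check_finite(x, "MEMD input")
  if (any(apply(x, 2, count_extrema) < 4)) {
    stop_data("degenerate MEMD input: a channel has fewer than 4 extrema")
  }
  dirs <- hammersley_directions(n_dirs, ncol(x))
  remainder <- unname(x)
  out <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  removed <- rep(list(integer()), ncol(x))
  names(removed) <- colnames(x)
  k <- 0L
  cap <- ceiling(log2(nrow(x))) + 4L
  while (k < cap) {
    step <- .memd_sift_cpp(remainder, dirs, 1L, as.integer(max_sift), tol)
    if (!length(step$imfs)) break
    k <- k + 1L
    imf <- step$imfs[[1]]
    remainder <- step$residual
    zcf <- apply(imf, 2, zero_crossing_freq, fs = fs)
    for (ch in seq_len(ncol(x))) {
      if (zcf[ch] >= cutoff_hz) {
        out[, ch] <- out[, ch] + imf[, ch]
      } else {
        removed[[ch]] <- c(removed[[ch]], k)
      }
    }
    if (early_stop && all(zcf < cutoff_hz)) break
  }
  removed <- lapply(removed, c, Inf)
  list(detrended = out, removed = removed, n_imfs = k)
}
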