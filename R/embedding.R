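# Delay-space reconstruction of the trunk dynamics with an AMI-selected lag.

#' Average mutual information curve of a tri-axial epoch
#'
#' Mutual information between `x(t)` and `x(t + tau)` is estimated per axis
#' from a joint equal-width histogram (bin edges fixed from the full signal
#' range, so the curve is invariant to affine rescaling) and averaged across
#' the AP/ML/V axes. Values are in nats.
#'
#' @param epoch an [accel_epoch()] or numeric N x 3 matrix.
#' @param max_lag largest lag examined, in samples.
#' @param bins histogram bins per margin.
#' @return List of class `ami_curve` with `lags` (0..max_lag) and `ami`.
#' @export
average_mutual_information <- function(epoch, max_lag = 100L, bins = 32L) {
  m <- as.matrix(epoch)
  n <- nrow(m)
  if (n <= 2L * max_lag) stop_config("epoch too short for max_lag")
  curves <- apply(m, 2, function(x) {
    rng <- range(x)
    if (diff(rng) == 0) stop_data("degenerate channel: constant signal")
    ix <- pmin(bins, floor((x - rng[1]) / diff(rng) * bins) + 1L)
    vapply(0:max_lag, function(tau) {
      i1 <- ix[1:(n - tau)]
      i2 <- ix[(1 + tau):n]
      nn <- length(i1)
      joint <- tabulate((i1 - 1L) * bins + i2, nbins = bins * bins) / nn
      px <- tabulate(i1, nbins = bins) / nn
      py <- tabulate(i2, nbins = bins) / nn
      nz <- joint > 0
      pxy <- outer(px, py)
      sum(joint[nz] * log(joint[nz] / t(pxy)[nz]))
    }, numeric(1))
  })
  structure(list(lags = 0:max_lag, ami = rowMeans(curves),
                 per_axis = curves),
            class = "ami_curve")
}

#' Select the embedding lag from an AMI curve
#'
#' The lag is the first `tau >= 1` at which the AMI decrease flattens below
#' `threshold` nats per sample, i.e. `ami[tau - 1] - ami[tau] < threshold`.
#' If no lag qualifies the first local minimum of the curve is used; the
#' result is always at least 1.
#'
#' @param curve an `ami_curve` from [average_mutual_information()].
#' @param threshold flattening threshold in nats per sample.
#' @return Integer lag in samples.
#' @export
select_lag <- function(curve, threshold = 0.01) {
  a <- curve$ami
  dec <- -diff(a)
  hit <- which(dec < threshold)
  if (length(hit)) return(as.integer(hit[1]))
  n <- length(a)
  lmin <- which(a[2:(n - 1)] < a[1:(n - 2)] & a[2:(n - 1)] <= a[3:n]) + 1L
  if (length(lmin)) return(as.integer(lmin[1] - 1L))
  as.integer(n - 1L)
}

#' Delay-embed a tri-axial signal into the 6- and 9-dimensional state spaces
#'
#' Row `j` of the 9-dimensional space is
#' `(AP_j, ML_j, V_j, AP_{j+l}, ML_{j+l}, V_{j+l}, AP_{j+2l}, ML_{j+2l},
#' V_{j+2l})`; the 6-dimensional space is its first six coordinates. Both are
#' built over the shared range `j = 1..N - 2l`, so every 9-dimensional row
#' has a 6-dimensional counterpart and the match-count inequality
#' `n_y <= n_x` holds structurally.
#'
#' @param epoch an [accel_epoch()] or numeric N x 3 matrix (AP, ML, V).
#' @param lag delay `l` in samples (`>= 1`).
#' @return An `embedded_pair` with `X` (T x 6), `Y` (T x 9), `lag`, and
#'   `row_index` mapping rows to original sample indices.
#' @export
embed_trunk <- function(epoch, lag) {
  m <- as.matrix(epoch)
  lag <- as.integer(lag)
  if (lag < 1) stop_config("lag must be >= 1")
  n <- nrow(m)
  if (n <= 2L * lag) stop_data("epoch too short for lag ", lag)
  tn <- n - 2L * lag
  j <- seq_len(tn)
  Y <- cbind(m[j, , drop = FALSE], m[j + lag, , drop = FALSE],
             m[j + 2L * lag, , drop = FALSE])
  colnames(Y) <- paste0(rep(AXES, 3), "_",
                        rep(c(0, 1, 2), each = 3), "l")
  new_embedded_pair(X = Y[, 1:6, drop = FALSE], Y = Y, lag = lag,
                    row_index = j)
}

#' Recover the original channels from an embedded pair
#'
#' Inverse of [embed_trunk()]: de-interleaves the delay blocks back into the
#' full-length tri-axial signal.
#'
#' @param pair an `embedded_pair`.
#' @return N x 3 matrix equal to the embedded input.
#' @export
unembed_trunk <- function(pair) {
  l <- pair$lag
  tn <- nrow(pair$Y)
  n <- tn + 2L * l
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, AXES))
  out[seq_len(tn), ] <- pair$Y[, 1:3]
  out[tn + seq_len(l), ] <- pair$Y[tn - l + seq_len(l), 4:6]
  out[tn + l + seq_len(l), ] <- pair$Y[tn - l + seq_len(l), 7:9]
  out
}
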