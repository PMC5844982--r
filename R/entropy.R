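# Generalized q-order sample entropy on phase-conditioned index sets and
# assembly of the PGME tensor.

#' Tsallis q-order logarithm
#'
#' `(n^(1-q) - 1) / (1 - q)`, continuously extended to the natural logarithm
#' at `q = 1`. Vectorized over `n` and `q`.
#'
#' @param n positive argument(s).
#' @param q deformation order(s).
#' @return Numeric vector of q-logarithms.
#' @export
qlog <- function(n, q) {
  if (any(n <= 0)) stop_config("qlog is defined for positive arguments only")
  r <- cbind(n, q)
  n <- r[, 1]; q <- r[, 2]
  out <- ifelse(abs(q - 1) < 1e-9, log(n), (n^(1 - q) - 1) / (1 - q))
  as.numeric(out)
}

#' Entropy configuration for PGME
#'
#' @param r_factor tolerance radius as a multiple of the mean across-axis SD
#'   of the raw epoch (one radius per epoch, shared by all scales, phases
#'   and q).
#' @param q_grid q-order grid; the default is 21 evenly spaced values on
#'   \[-1, 1\].
#' @param scales temporal scales (coarse-graining levels) evaluated.
#' @param phases step-cycle phase onsets in percent.
#' @param width phase-window width as a fraction of the cycle duration.
#' @param theiler temporal exclusion half-width for match counting (samples).
#' @param n_dirs,max_sift MEMD settings used inside [pgme_epoch()].
#' @param max_lag,bins AMI settings used for lag selection.
#' @param min_cycles minimum number of valid cycles required per epoch.
#' @param match_scope `"window"` restricts both templates and candidates to
#'   the phase window (default); `"anywhere"` keeps templates in the window
#'   but allows candidates anywhere in the epoch.
#' @return Named list of entropy settings.
#' @export
entropy_config <- function(r_factor = 0.3,
                           q_grid = seq(-1, 1, length.out = 21),
                           scales = 1:6, phases = c(0, 20, 40, 60, 80),
                           width = 0.10, theiler = 0L, n_dirs = 64,
                           max_sift = 15, max_lag = 100L, bins = 32L,
                           min_cycles = 10L,
                           match_scope = c("window", "anywhere")) {
  stopifnot(r_factor > 0)
  list(r_factor = r_factor, q_grid = q_grid, scales = scales,
       phases = phases, width = width, theiler = as.integer(theiler),
       n_dirs = n_dirs, max_sift = max_sift, max_lag = max_lag, bins = bins,
       min_cycles = min_cycles, match_scope = match.arg(match_scope))
}

chebyshev_cross <- function(A, B) {
  D <- abs(outer(A[, 1], B[, 1], "-"))
  for (c in 2:ncol(A)) D <- pmax(D, abs(outer(A[, c], B[, c], "-")))
  D
}

#' Count state-space matches within an index set
#'
#' Over ordered pairs `(i, j)` of rows indexed by `index_set` with `i != j`
#' and `|i - j| > theiler` (in original sample time), `n_x` is the fraction
#' whose 6-dimensional rows are within max-norm distance `r`, and `n_y` the
#' same for the 9-dimensional rows. Both fractions share the same
#' denominator, so `n_y <= n_x` always (a 9-coordinate match implies its
#' 6-coordinate subset matches).
#'
#' @param pair an `embedded_pair` (possibly coarse-grained), or a list with
#'   `X`, `Y`, `row_index`.
#' @param index_set sample indices (in `row_index` units) of the template
#'   points; `NULL` uses all rows.
#' @param r tolerance radius (`> 0`).
#' @param theiler temporal exclusion half-width (samples).
#' @param candidate_set optional sample indices of candidate points; default
#'   equal to `index_set` (matches confined to the window).
#' @return List of class `match_counts`: `n_x`, `n_y`, `pairs_evaluated`,
#'   `defined`.
#' @export
count_matches <- function(pair, index_set = NULL, r, theiler = 0L,
                          candidate_set = NULL) {
  if (r <= 0) stop_config("r must be positive")
  rows <- pair$row_index
  if (is.null(index_set)) index_set <- rows
  if (is.null(candidate_set)) candidate_set <- index_set
  ti <- match(index_set, rows)
  tc <- match(candidate_set, rows)
  if (anyNA(ti) || anyNA(tc)) {
    stop_config("index_set outside the shared row range of the embedding")
  }
  if (length(ti) < 2) stop_data("insufficient points: index set has < 2 rows")
  admissible <- abs(outer(index_set, candidate_set, "-")) > theiler
  denom <- sum(admissible)
  if (denom == 0) stop_data("insufficient points: no admissible pairs")
  Dx <- chebyshev_cross(pair$X[ti, , drop = FALSE],
                        pair$X[tc, , drop = FALSE])
  Dy <- chebyshev_cross(pair$Y[ti, , drop = FALSE],
                        pair$Y[tc, , drop = FALSE])
  n_x <- sum(Dx <= r & admissible) / denom
  n_y <- sum(Dy <= r & admissible) / denom
  structure(list(n_x = n_x, n_y = n_y, pairs_evaluated = denom,
                 defined = n_y > 0),
            class = "match_counts")
}

#' Generalized sample entropy from match counts
#'
#' `qSaEn = qlog(n_x) - qlog(n_y)`; at `q = 1` this is the conventional
#' sample entropy `ln(n_x / n_y)`. Undefined counts (`n_y = 0`) propagate as
#' `NA`.
#'
#' @param counts a `match_counts` object from [count_matches()].
#' @param q q-order(s); vectorized.
#' @return Numeric vector of entropies (`NA` where undefined).
#' @export
qsaen <- function(counts, q) {
  if (!isTRUE(counts$defined)) return(rep(NA_real_, length(q)))
  qlog(counts$n_x, q) - qlog(counts$n_y, q)
}

#' Phase-dependent generalized multiscale entropy of one epoch
#'
#' Runs the full per-epoch pipeline: embedding lag from the AMI flattening
#' rule on the raw acceleration; 9-dimensional delay embedding; MEMD of the
#' embedded dynamics; for each scale k the coarse-grained series (signal
#' minus the first k-1 IMFs); and, within each step-cycle phase window,
#' match counting at radius `r = r_factor *` mean across-axis SD of the raw
#' epoch, followed by evaluation of the whole q grid from the shared counts.
#'
#' @param epoch an [accel_epoch()].
#' @param cycles a `step_cycles` object; computed from the epoch (velocity
#'   integration + vertical-velocity minima) when `NULL`.
#' @param cfg an [entropy_config()].
#' @return A `pgme_tensor` (scale x phase x q array, `NA` = missing) with
#'   lag, radius and IMF count in its `meta` attribute.
#' @export
pgme_epoch <- function(epoch, cycles = NULL, cfg = entropy_config()) {
  fs <- epoch_fs(epoch)
  m <- epoch_matrix(epoch)
  if (is.null(cycles)) {
    vel <- estimate_velocity(epoch, n_dirs = cfg$n_dirs,
                             max_sift = cfg$max_sift)
    cycles <- detect_step_cycles(vel)
  }
  if (sum(cycles$valid) < cfg$min_cycles) {
    stop_data("epoch has fewer than ", cfg$min_cycles, " valid cycles")
  }
  ami <- average_mutual_information(m, max_lag = cfg$max_lag,
                                    bins = cfg$bins)
  lag <- select_lag(ami)
  emb <- embed_trunk(m, lag)
  r <- cfg$r_factor * mean(apply(m, 2, sd))
  k_max <- max(cfg$scales)
  dec <- memd(emb$Y, n_dirs = cfg$n_dirs, max_sift = cfg$max_sift,
              max_imf = k_max, fs = fs)
  windows <- phase_windows(cycles, phases = cfg$phases, width = cfg$width)
  tn <- nrow(emb$Y)
  nq <- length(cfg$q_grid)
  vals <- array(NA_real_,
                dim = c(length(cfg$scales), length(cfg$phases), nq),
                dimnames = list(scale = cfg$scales, phase = cfg$phases,
                                q = signif(cfg$q_grid, 3)))
  dbar <- emb$Y
  for (si in seq_along(cfg$scales)) {
    k <- cfg$scales[si]
    # d-bar_k = Y - sum of IMFs below k (telescoping form of the IMF sum);
    # available only when the decomposition reached at least k modes
    if (k > 1) {
      if (k - 1 > dec$M) next
      dbar <- emb$Y
      for (i in seq_len(k - 1)) dbar <- dbar - dec$imfs[[i]]
    }
    cg_pair <- list(X = dbar[, 1:6, drop = FALSE], Y = dbar,
                    row_index = emb$row_index)
    for (pi in seq_along(cfg$phases)) {
      idx <- windows$index_sets[[pi]]
      idx <- idx[idx <= tn]
      if (length(idx) < 2) next
      cand <- if (cfg$match_scope == "anywhere") emb$row_index else idx
      counts <- tryCatch(
        count_matches(cg_pair, idx, r = r, theiler = cfg$theiler,
                      candidate_set = cand),
        pgme_data_error = function(e) NULL)
      if (is.null(counts)) next
      vals[si, pi, ] <- qsaen(counts, cfg$q_grid)
    }
  }
  new_pgme_tensor(vals, level = "epoch",
                  meta = list(lag = lag, r = r, n_imfs = dec$M, fs = fs,
                              n_valid_cycles = sum(cycles$valid)))
}

#' Subject-level PGME: elementwise median across epochs
#'
#' Missing cells are ignored; a cell is missing at the subject level when
#' more than half of the epochs are missing there.
#'
#' @param tensors list of epoch-level `pgme_tensor` objects with identical
#'   dimensions.
#' @return A subject-level `pgme_tensor`.
#' @export
pgme_subject <- function(tensors) {
  if (!length(tensors)) stop_config("no epoch tensors given")
  arr <- simplify2array(lapply(tensors, unclass))
  dim(arr) <- c(dim(tensors[[1]]), length(tensors))
  med <- apply(arr, 1:3, function(v) {
    if (mean(is.na(v)) > 0.5) NA_real_ else median(v, na.rm = TRUE)
  })
  dimnames(med) <- dimnames(tensors[[1]])
  new_pgme_tensor(med, level = "subject",
                  meta = list(n_epochs = length(tensors)))
}

#' Per-cell group contrast of PGME tensors
#'
#' Two-sided Wilcoxon rank-sum test per (scale, phase, q) cell between two
#' groups of subject-level tensors, with Benjamini-Hochberg step-up control
#' of the false discovery rate across all tested cells. Cells with fewer
#' than two non-missing values in either group are skipped and excluded
#' from the correction.
#'
#' @param group_a,group_b lists of subject-level `pgme_tensor` objects.
#' @param fdr false-discovery-rate level for the significance flag.
#' @return data.frame with one row per tested cell: scale, phase, q, group
#'   medians, `p`, BH-adjusted `p_adj`, and `significant`.
#' @export
group_compare <- function(group_a, group_b, fdr = 0.05) {
  dn <- dimnames(group_a[[1]])
  grid <- expand.grid(si = seq_along(dn$scale), pi = seq_along(dn$phase),
                      qi = seq_along(dn$q))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    si <- grid$si[g]; pi <- grid$pi[g]; qi <- grid$qi[g]
    va <- vapply(group_a, function(t) t[si, pi, qi], numeric(1))
    vb <- vapply(group_b, function(t) t[si, pi, qi], numeric(1))
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) < 2 || length(vb) < 2) return(NULL)
    p <- suppressWarnings(wilcox.test(va, vb, exact = FALSE)$p.value)
    data.frame(scale = as.numeric(dn$scale[si]),
               phase = as.numeric(dn$phase[pi]),
               q = as.numeric(dn$q[qi]),
               median_a = median(va), median_b = median(vb), p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) {
    return(data.frame(scale = numeric(), phase = numeric(), q = numeric(),
                      median_a = numeric(), median_b = numeric(),
                      p = numeric(), p_adj = numeric(),
                      significant = logical()))
  }
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < fdr
  out
}

#' Flatten a subject-level PGME tensor to a named feature vector
#'
#' @param tensor a `pgme_tensor`.
#' @return Named numeric vector, names `pgme_k<scale>_p<phase>_q<q>`.
#' @export
pgme_flatten <- function(tensor) {
  dn <- dimnames(tensor)
  grid <- expand.grid(scale = dn$scale, phase = dn$phase, q = dn$q,
                      stringsAsFactors = FALSE)
  v <- as.vector(unclass(tensor))
  names(v) <- sprintf("pgme_k%s_p%s_q%s", grid$scale, grid$phase, grid$q)
  v
}
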