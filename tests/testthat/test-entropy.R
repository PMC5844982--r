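test_that("q-logarithm identities hold exactly", {
  qs <- seq(-1, 1, by = 0.1)
  expect_equal(qlog(rep(1, length(qs)), qs), rep(0, length(qs)))
  expect_identical(qlog(0.5, 0), -0.5)
  expect_equal(qlog(exp(1), 1), 1)
  expect_identical(qlog(4, -1), 7.5)
  expect_error(qlog(0, 0.5), class = "pgme_config_error")
  expect_error(qlog(-1, 0.5), class = "pgme_config_error")
})

test_that("q-logarithm is non-increasing in q for any fixed argument", {
  # d/dq log_q(n) <= 0 for every n > 0, with equality only at n = 1
  grid <- seq(-1, 1, length.out = 21)
  for (n in c(0.1, 0.4, 0.99, 1, 1.01, 2.5, 10)) {
    v <- qlog(rep(n, 21), grid)
    expect_true(all(diff(v) <= 1e-12))
    if (n == 1) expect_true(all(v == 0))
  }
})

test_that("match counting equals the brute-force oracle on toy embeddings", {
  set.seed(21)
  for (i in 1:5) {
    X <- matrix(rnorm(10 * 6), 10)
    Y <- cbind(X, matrix(rnorm(10 * 3), 10))
    pair <- list(X = X, Y = Y, row_index = 1:10)
    for (theiler in c(0L, 2L)) {
      r <- 1.2
      got <- count_matches(pair, 1:10, r = r, theiler = theiler)
      want <- brute_match_counts(X, Y, 1:10, r, theiler)
      expect_identical(got$n_x, want$n_x)
      expect_identical(got$n_y, want$n_y)
      expect_identical(got$pairs_evaluated, want$pairs)
    }
  }
})

test_that("constant signals match everywhere; n_y never exceeds n_x", {
  pair <- list(X = matrix(1, 8, 6), Y = matrix(1, 8, 9), row_index = 1:8)
  got <- count_matches(pair, 1:8, r = 0.1)
  expect_identical(got$n_x, 1)
  expect_identical(got$n_y, 1)
  set.seed(22)
  for (i in 1:20) {
    X <- matrix(rnorm(30 * 6), 30)
    Y <- cbind(X, matrix(rnorm(30 * 3), 30))
    got <- count_matches(list(X = X, Y = Y, row_index = 1:30), 1:30, r = 0.8)
    expect_lte(got$n_y, got$n_x)
  }
})

test_that("match counting rejects undersized or out-of-range index sets", {
  pair <- list(X = matrix(rnorm(60), 10), Y = matrix(rnorm(90), 10),
               row_index = 1:10)
  expect_error(count_matches(pair, 5, r = 1), class = "pgme_data_error")
  expect_error(count_matches(pair, c(1, 99), r = 1),
               class = "pgme_config_error")
  expect_error(count_matches(pair, 1:10, r = -1),
               class = "pgme_config_error")
})

test_that("qsaen matches closed forms and flags undefined counts", {
  mk <- function(nx, ny) structure(list(n_x = nx, n_y = ny,
                                        pairs_evaluated = 100L,
                                        defined = ny > 0),
                                   class = "match_counts")
  expect_equal(qsaen(mk(0.5, 0.25), 1), log(2))
  expect_identical(qsaen(mk(0.5, 0.25), 0), 0.25)
  expect_true(all(qsaen(mk(0.4, 0.4), seq(-1, 1, 0.1)) == 0))
  expect_true(is.na(qsaen(mk(0.5, 0), 1)))
})

test_that("evaluating the q grid from shared counts equals per-q recomputation", {
  set.seed(23)
  X <- matrix(rnorm(40 * 6), 40)
  Y <- cbind(X, matrix(rnorm(40 * 3), 40))
  pair <- list(X = X, Y = Y, row_index = 1:40)
  counts <- count_matches(pair, 1:40, r = 1.5)
  grid <- seq(-1, 1, length.out = 21)
  shared <- qsaen(counts, grid)
  per_q <- vapply(grid, function(q) {
    qsaen(count_matches(pair, 1:40, r = 1.5), q)
  }, numeric(1))
  expect_identical(shared, per_q)
})

test_that("q = 1 whole-epoch entropy equals the brute-force sample entropy", {
  set.seed(24)
  for (i in 1:3) {
    m <- matrix(rnorm(200 * 3), ncol = 3,
                dimnames = list(NULL, c("AP", "ML", "V")))
    lag <- 4L
    emb <- embed_trunk(m, lag)
    r <- 0.3 * mean(apply(m, 2, sd))
    counts <- count_matches(emb, NULL, r = r)
    want <- brute_sampen(m, lag, r)
    expect_equal(qsaen(counts, 1), want, tolerance = 1e-12)
  }
})

test_that("white noise is more irregular than a tone at equal radius", {
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    noise <- matrix(rnorm(400 * 3), ncol = 3)
    colnames(noise) <- c("AP", "ML", "V")
    tone <- as.matrix(tone_epoch(duration = 4, noise = 0.01))
    scale_to <- function(m) sweep(m, 2, apply(m, 2, sd), "/")
    en <- function(m) {
      emb <- embed_trunk(scale_to(m), 4L)
      qsaen(count_matches(emb, NULL, r = 1.0), 1)
    }
    en(noise) > en(tone)
  }, logical(1))
  expect_true(all(wins))
})

test_that("epoch tensors have the full scale-phase-q shape", {
  sim <- simulate_epoch(quick_params(duration = 10), seed = 31)
  cfg <- quick_entropy_cfg(scales = 1:6,
                           q_grid = seq(-1, 1, length.out = 21),
                           n_dirs = 16)
  tens <- pgme_epoch(sim$epoch, cfg = cfg)
  expect_identical(dim(unclass(tens)), c(6L, 5L, 21L))
  meta <- attr(tens, "meta")
  expect_gte(meta$lag, 1L)
  expect_gt(meta$r, 0)
  # defined cells are finite; undefined are NA, never Inf
  expect_true(all(is.finite(tens) | is.na(tens)))
})

test_that("phase pooling is order-free over cycles", {
  sim <- simulate_epoch(quick_params(duration = 8), seed = 32)
  vel <- estimate_velocity(sim$epoch, n_dirs = 8)
  cyc <- detect_step_cycles(vel)
  cfg <- quick_entropy_cfg()
  t1 <- pgme_epoch(sim$epoch, cyc, cfg)
  # same boundaries, cycle bookkeeping rebuilt: identical windows
  cyc2 <- structure(list(boundaries = cyc$boundaries,
                         durations = cyc$durations, valid = cyc$valid,
                         fs = cyc$fs), class = "step_cycles")
  t2 <- pgme_epoch(sim$epoch, cyc2, cfg)
  expect_identical(unclass(t1), unclass(t2))
})

test_that("noise injected at one phase raises entropy there", {
  hits <- vapply(1:20, function(s) {
    prof <- rep(1, 5); prof[4] <- 2  # extra irregularity at the 60% bin
    sim <- simulate_epoch(quick_params(duration = 30,
                                       phase_noise_profile = prof),
                          seed = 900 + s)
    cfg <- quick_entropy_cfg(scales = 1, q_grid = 1)
    tens <- pgme_epoch(sim$epoch, cfg = cfg)
    tens[1, 4, 1] > tens[1, 1, 1]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("subject aggregation is an elementwise median with missing rules", {
  mk <- function(vals) {
    a <- array(vals, dim = c(1, 1, 3),
               dimnames = list(scale = "1", phase = "0",
                               q = c("-1", "0", "1")))
    pgme:::new_pgme_tensor(a, level = "epoch")
  }
  single <- pgme_subject(list(mk(c(1, 2, 3))))
  expect_equal(as.vector(single), c(1, 2, 3))
  med <- pgme_subject(list(mk(c(1, 1, 1)), mk(c(2, 5, 2)), mk(c(9, 3, 4))))
  expect_equal(as.vector(med), c(2, 3, 2))
  # > 50% missing in a cell makes the subject cell missing
  mix <- pgme_subject(list(mk(c(1, NA, NA)), mk(c(2, NA, 4)),
                           mk(c(3, 7, NA))))
  expect_equal(as.vector(mix), c(2, NA, NA))
  expect_error(pgme_subject(list()), class = "pgme_config_error")
})

test_that("group comparison controls false discoveries and finds real shifts", {
  mk_group <- function(n, shift_cell = FALSE, seed) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      a <- array(rnorm(3 * 5 * 3), dim = c(3, 5, 3),
                 dimnames = list(scale = 1:3, phase = c(0, 20, 40, 60, 80),
                                 q = c(-1, 0, 1)))
      if (shift_cell) a[1, 4, 2] <- a[1, 4, 2] + 2 * sqrt(2)
      pgme:::new_pgme_tensor(a, level = "subject")
    })
  }
  # identical distributions: discovery proportion over 50 null repeats
  fdp <- vapply(1:50, function(r) {
    res <- group_compare(mk_group(20, seed = 2 * r), mk_group(20, seed = 2 * r + 1))
    mean(res$significant)
  }, numeric(1))
  expect_lte(mean(fdp), 0.05)
  # a 2-pooled-SD shift in one cell is found nearly always
  found <- vapply(1:30, function(r) {
    res <- group_compare(mk_group(20, TRUE, seed = 1000 + 2 * r),
                         mk_group(20, seed = 1001 + 2 * r))
    any(res$significant[res$scale == 1 & res$phase == 60 & res$q == 0])
  }, logical(1))
  expect_gte(mean(found), 0.95)
})

test_that("group_compare adjusts p-values by the BH step-up rule", {
  # independent step-up oracle: adj_(i) = min_{j >= i} min(1, m p_(j) / j)
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- pmin(1, p[o] * m / seq_len(m))
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- adj
    out
  }
  expect_equal(bh_oracle(c(0.01, 0.03, 0.04)), c(0.03, 0.04, 0.04))
  set.seed(26)
  grp <- function(seed) {
    set.seed(seed)
    lapply(1:8, function(i) {
      a <- array(rnorm(2 * 2 * 2), dim = c(2, 2, 2),
                 dimnames = list(scale = 1:2, phase = c(0, 60), q = c(0, 1)))
      pgme:::new_pgme_tensor(a, level = "subject")
    })
  }
  res <- group_compare(grp(1), grp(2))
  expect_equal(res$p_adj, bh_oracle(res$p), tolerance = 1e-12)
})

test_that("flattening names every tensor cell", {
  sim <- simulate_epoch(quick_params(), seed = 33)
  tens <- pgme_epoch(sim$epoch, cfg = quick_entropy_cfg())
  v <- pgme_flatten(pgme_subject(list(tens)))
  expect_length(v, 3 * 5 * 3)
  expect_true(all(grepl("^pgme_k[0-9]+_p[0-9]+_q", names(v))))
})
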