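test_that("holdouts keep pairs together and labels balanced", {
  coh <- toy_cohort(n_pairs = 10)
  hs <- make_holdouts(coh, n_reps = 10, train_frac = 0.8, seed = 5)
  for (h in hs) {
    expect_length(h$train, 16)
    expect_length(h$test, 4)
    expect_equal(mean(coh$subjects$label[h$test]), 0.5)
    # no pair split across train and test
    expect_length(intersect(coh$subjects$pair_id[h$train],
                            coh$subjects$pair_id[h$test]), 0)
  }
  again <- make_holdouts(coh, n_reps = 10, train_frac = 0.8, seed = 5)
  expect_identical(hs, again)
  other <- make_holdouts(coh, n_reps = 10, train_frac = 0.8, seed = 6)
  expect_false(identical(hs, other))
  expect_error(make_holdouts(toy_cohort(n_pairs = 2), train_frac = 0.9),
               class = "pgme_config_error")
})

test_that("NIPALS recovers a rank-one structure and orthogonal scores", {
  set.seed(51)
  t_true <- rnorm(40)
  p_true <- rnorm(12)
  X <- t_true %*% t(p_true)
  fit <- nipals_pls(X, t_true, n_components = 1)
  expect_gt(abs(cor(fit$scores[, 1], t_true)), 1 - 1e-8)
  X2 <- matrix(rnorm(40 * 8), 40)
  y2 <- rnorm(40)
  fit2 <- nipals_pls(scale(X2), y2, n_components = 5)
  gram <- crossprod(fit2$scores)
  off <- abs(gram[upper.tri(gram)]) / max(diag(gram))
  expect_lt(max(off), 1e-8)
})

test_that("full-component NIPALS reproduces the least-squares fit", {
  set.seed(52)
  X <- scale(matrix(rnorm(30 * 6), 30))
  y <- rnorm(30)
  fit <- nipals_pls(X, y, n_components = 6)
  b <- pgme:::pls_coefficients(fit)
  fitted_pls <- drop(X %*% b)
  fitted_ls <- drop(X %*% coef(lm(y ~ X - 1)))
  expect_equal(fitted_pls, fitted_ls, tolerance = 1e-6)
})

test_that("NIPALS refuses zero-variance features by name", {
  X <- cbind(good = rnorm(20), dead = rep(1, 20))
  expect_error(nipals_pls(X, rnorm(20), 2), "dead")
})

test_that("PLS-DA separates Gaussian clouds and not permuted labels", {
  coh <- toy_cohort(n_pairs = 20, delta = 3, seed = 53)
  y <- coh$subjects$label
  fit <- fit_plsda(coh$features, y, seed = 11)
  train_acc <- mean(predict(fit, coh$features)$class == y)
  expect_gte(train_acc, 0.99)
  set.seed(54)
  accs <- vapply(1:5, function(i) {
    yp <- sample(y)
    mean(1 - pgme:::cv_pls_error(coh$features, yp, max_components = 5,
                                 seed = i)$error)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("a single informative feature drives component selection", {
  picks <- vapply(1:10, function(s) {
    set.seed(700 + s)
    n <- 60
    y <- rep(0:1, n / 2)
    X <- cbind(inform = y * 2 + rnorm(n, 0, 0.8),
               matrix(rnorm(n * 6), n))
    colnames(X)[2:7] <- paste0("noise", 1:6)
    fit_plsda(X, y, max_components = 5, seed = s)$n_components
  }, numeric(1))
  expect_gte(mean(picks == 1), 0.8)
})

test_that("TP loadings rank informative features first", {
  top_rank <- vapply(1:10, function(s) {
    set.seed(800 + s)
    n <- 60
    y <- rep(0:1, n / 2)
    X <- cbind(inform = y * 2 + rnorm(n, 0, 0.5),
               matrix(rnorm(n * 9), n))
    colnames(X)[2:10] <- paste0("noise", 1:9)
    fit <- fit_plsda(X, y, max_components = 5, seed = s)
    tp <- tp_loadings(fit)
    which(tp$feature == "inform")
  }, integer(1))
  expect_gte(mean(top_rank == 1), 0.9)
})

test_that("duplicated features receive identical TP loadings", {
  set.seed(55)
  n <- 40
  y <- rep(0:1, n / 2)
  base <- y + rnorm(n, 0, 0.5)
  X <- cbind(a_twin = base, b_twin = base, c_noise = rnorm(n))
  fit <- fit_plsda(X, y, max_components = 2, seed = 1)
  tp <- tp_loadings(fit)
  expect_lt(abs(tp$tp_loading[tp$feature == "a_twin"] -
                  tp$tp_loading[tp$feature == "b_twin"]), 1e-10)
  # deterministic tie-break by name
  expect_lt(which(tp$feature == "a_twin"), which(tp$feature == "b_twin"))
})

test_that("backward selection keeps informative features and is bookkept", {
  kept <- vapply(1:8, function(s) {
    set.seed(900 + s)
    n <- 50
    y <- rep(0:1, n / 2)
    X <- cbind(inf1 = y * 1.5 + rnorm(n, 0, 0.6),
               inf2 = y * 1.5 + rnorm(n, 0, 0.6),
               matrix(rnorm(n * 8), n))
    colnames(X)[3:10] <- paste0("noise", 1:8)
    sel <- backward_select(X, y, max_components = 5, seed = s)
    all(c("inf1", "inf2") %in% sel$selected)
  }, logical(1))
  expect_gte(mean(kept), 0.8)
  # trace is internally consistent and single features pass through
  set.seed(56)
  X1 <- cbind(only = rnorm(20))
  y1 <- rep(0:1, 10)
  res <- backward_select(X1, y1, seed = 1)
  expect_identical(res$selected, "only")
  set.seed(57)
  Xs <- cbind(a = rnorm(30) + rep(0:1, 15), b = rnorm(30), c = rnorm(30))
  tr <- backward_select(Xs, rep(0:1, 15), max_components = 2,
                        seed = 3)$trace
  expect_identical(tr$n_features, c(3L, 2L, 1L))
  expect_identical(tr$step, 0:2)
})

test_that("confusion rates match hand arithmetic", {
  r <- pgme:::confusion_rates(tp = 3, fn = 2, tn = 4, fp = 1)
  expect_equal(unname(r), c(0.7, 0.6, 0.8, 0.75, 2 / 3))
})

test_that("evaluation reports perfect separation with zero-width CIs", {
  coh <- toy_cohort(n_pairs = 15, delta = 8, n_noise = 2, seed = 58)
  hs <- make_holdouts(coh, n_reps = 20, seed = 2)
  rep_ <- evaluate_plsda(coh, hs, max_components = 3, n_boot = 200,
                         seed = 3)
  expect_true(all(rep_$means == 1))
  expect_true(all(rep_$ci[2, ] - rep_$ci[1, ] == 0))
  # bootstrap CI brackets the point estimate in general
  coh2 <- toy_cohort(n_pairs = 15, delta = 1.2, seed = 59)
  rep2 <- evaluate_plsda(coh2, make_holdouts(coh2, n_reps = 15, seed = 4),
                         max_components = 3, n_boot = 200, seed = 5)
  expect_true(all(rep2$ci[1, ] <= rep2$means + 1e-12))
  expect_true(all(rep2$ci[2, ] >= rep2$means - 1e-12))
})

test_that("AICc arithmetic and relative likelihood are exact", {
  expect_equal(aicc(-10, 2, 20), 24 + 12 / 17)
  expect_true(is.na(aicc(-10, 19, 20)))
  mk <- function(ll, k) structure(list(mean_n_components = k - 1,
                                       loglik = ll, n_obs = 20),
                                  class = "performance_report")
  cmp <- aicc_compare(list(a = mk(-10, 2), b = mk(-10, 2)))
  expect_equal(cmp$delta["a", "b"], 0)
  expect_equal(cmp$rel_likelihood["a", "b"], 1)
  # better likelihood at equal k gives lower AICc
  cmp2 <- aicc_compare(list(good = mk(-8, 2), bad = mk(-10, 2)))
  expect_lt(cmp2$table$aicc[1], cmp2$table$aicc[2])
})

test_that("repeated evaluation under one seed is byte-identical", {
  coh <- toy_cohort(n_pairs = 12, delta = 2, seed = 60)
  hs <- make_holdouts(coh, n_reps = 8, seed = 9)
  r1 <- evaluate_plsda(coh, hs, max_components = 3, n_boot = 100, seed = 7)
  r2 <- evaluate_plsda(coh, hs, max_components = 3, n_boot = 100, seed = 7)
  expect_identical(r1, r2)
})
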