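# Matched-pair PLS-DA fall-prediction pipeline: stratified holdouts, NIPALS
# PLS, LDA on latent scores, TP-loading ranking, backward feature
# elimination, performance evaluation with bootstrap CIs, AICc comparison.

#' Matched-pair stratified holdout splits
#'
#' Each repetition assigns whole matched pairs to train or test (pairs are
#' never split), which keeps the faller fraction of every test set at
#' exactly one half.
#'
#' @param cohort a [cohort_table()].
#' @param n_reps number of repetitions.
#' @param train_frac fraction of pairs in the training set.
#' @param seed integer seed; splits are reproducible.
#' @return List of length `n_reps`; each element has `train` and `test`
#'   subject row indices.
#' @export
make_holdouts <- function(cohort, n_reps = 500, train_frac = 0.8,
                          seed = 1L) {
  subj <- cohort$subjects
  pairs <- unique(subj$pair_id)
  n_test <- round((1 - train_frac) * length(pairs))
  if (n_test < 1 || n_test >= length(pairs)) {
    stop_config("cohort too small for the requested train fraction")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n_reps), function(i) {
    test_pairs <- sample(pairs, n_test)
    test <- which(subj$pair_id %in% test_pairs)
    list(train = setdiff(seq_len(nrow(subj)), test), test = test)
  })
}

#' NIPALS partial least squares (single response)
#'
#' Standard NIPALS PLS1: per component, iterate weight `w = X'u / |X'u|`,
#' score `t = X w`, loading `p = X't / t't`, then deflate `X` and `y`.
#' Scores are mutually orthogonal by construction.
#'
#' @param X predictor matrix (rows = subjects), already Z-scored.
#' @param y numeric response (e.g. 0/1 labels).
#' @param n_components number of latent components.
#' @param tol inner-iteration convergence tolerance.
#' @param max_iter inner-iteration cap.
#' @return List of class `pls_model`: `weights` W, `loadings` P, `scores` T,
#'   `y_loadings` q, `coefficients` (regression vector on the original
#'   features, per component count), plus centering info.
#' @export
nipals_pls <- function(X, y, n_components, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X)
  zero_var <- which(apply(X, 2, stats::var) == 0)
  if (length(zero_var)) {
    stop_config("zero-variance feature(s): ",
                paste(colnames(X)[zero_var], collapse = ", "))
  }
  p <- ncol(X)
  n_components <- min(n_components, p, nrow(X) - 1L)
  Xd <- X; yd <- as.numeric(y)
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(X), n_components)
  qv <- numeric(n_components)
  actual <- 0L
  for (a in seq_len(n_components)) {
    u <- yd
    t_old <- rep(Inf, nrow(X))
    tt <- rep(0, nrow(X)); nw <- 0
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      tt <- Xd %*% w
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    if (nw < 1e-14 || sum(tt^2) < 1e-14) break
    pp <- crossprod(Xd, tt) / sum(tt^2)
    qq <- sum(yd * tt) / sum(tt^2)
    Xd <- Xd - tt %*% t(pp)
    yd <- yd - qq * tt
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; qv[a] <- qq
    actual <- a
  }
  if (actual == 0L) stop_data("NIPALS extracted no components")
  W <- W[, seq_len(actual), drop = FALSE]
  P <- P[, seq_len(actual), drop = FALSE]
  Tm <- Tm[, seq_len(actual), drop = FALSE]
  qv <- qv[seq_len(actual)]
  R <- W %*% solve(crossprod(P, W))   # X-score projection matrix
  structure(list(weights = W, loadings = P, scores = Tm, y_loadings = qv,
                 rotation = R, n_components = actual,
                 feature_names = colnames(X)),
            class = "pls_model")
}

pls_scores <- function(model, Xnew, ncomp = model$n_components) {
  as.matrix(Xnew) %*% model$rotation[, seq_len(ncomp), drop = FALSE]
}

pls_coefficients <- function(model, ncomp = model$n_components) {
  a <- seq_len(ncomp)
  drop(model$rotation[, a, drop = FALSE] %*% model$y_loadings[a])
}

# z-scoring with training statistics only
ztrain <- function(Xtr, Xte = NULL) {
  mu <- colMeans(Xtr)
  sg <- apply(Xtr, 2, sd)
  sg[sg == 0] <- 1
  out <- list(train = sweep(sweep(Xtr, 2, mu), 2, sg, "/"))
  if (!is.null(Xte)) out$test <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
  out
}

cv_folds_idx <- function(n, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  split(sample(seq_len(n)), rep(seq_len(folds), length.out = n))
}

# CV misclassification error for each component count 1..max_comp;
# PLS + LDA trained per fold, z-scoring inside the fold
cv_pls_error <- function(X, y, max_components = 10, folds = 10,
                         seed = 1L) {
  n <- nrow(X)
  folds <- min(folds, n)
  idx <- cv_folds_idx(n, folds, seed = seed)
  max_c <- min(max_components, ncol(X), n - max(lengths(idx)) - 1L)
  max_c <- max(max_c, 1L)
  err <- matrix(NA_real_, length(idx), max_c)
  for (f in seq_along(idx)) {
    te <- idx[[f]]; tr <- setdiff(seq_len(n), te)
    if (length(unique(y[tr])) < 2) next
    keep <- which(apply(X[tr, , drop = FALSE], 2, stats::var) > 0)
    if (length(keep) < 1) next
    z <- ztrain(X[tr, keep, drop = FALSE], X[te, keep, drop = FALSE])
    model <- tryCatch(nipals_pls(z$train, y[tr], max_c),
                      error = function(e) NULL)
    if (is.null(model)) next
    for (a in seq_len(model$n_components)) {
      pred <- plsda_predict_scores(model, z$train, y[tr], z$test, a)
      if (is.null(pred)) next
      err[f, a] <- mean(pred != y[te])
    }
  }
  mean_err <- colMeans(err, na.rm = TRUE)
  mean_err[!is.finite(mean_err)] <- 1
  # one-standard-error rule: smallest component count whose CV error is
  # within one SE (across folds) of the minimum
  best <- which.min(mean_err)
  se <- stats::sd(err[, best], na.rm = TRUE) / sqrt(sum(!is.na(err[, best])))
  if (!is.finite(se)) se <- 0
  chosen <- which(mean_err <= mean_err[best] + se)[1]
  list(error = mean_err[chosen], n_components = chosen,
       per_component = mean_err)
}

# LDA with pooled covariance on training scores; 0.5 posterior threshold
plsda_predict_scores <- function(model, Ztr, ytr, Zte, ncomp) {
  str <- pls_scores(model, Ztr, ncomp)
  ste <- pls_scores(model, Zte, ncomp)
  # scores are orthogonal; lda's collinearity warning only flags a
  # near-zero-variance trailing component
  lda_fit <- tryCatch(suppressWarnings(MASS::lda(str,
                                                 grouping = factor(ytr))),
                      error = function(e) NULL)
  if (is.null(lda_fit)) return(NULL)
  post <- predict(lda_fit, ste)$posterior
  as.integer(post[, "1"] >= 0.5)
}

#' Fit a PLS-DA classifier with internally cross-validated component count
#'
#' NIPALS PLS on the Z-scored training features, linear discriminant
#' analysis with pooled covariance on the latent scores, classification at
#' posterior 0.5. The number of components (at most `max_components`) is
#' chosen by internal 10-fold cross-validated misclassification error.
#'
#' @param X training feature matrix (raw scale; Z-scoring is internal).
#' @param y 0/1 labels.
#' @param max_components latent-vector search cap.
#' @param folds internal CV folds.
#' @param seed seed for the internal fold assignment.
#' @return List of class `plsda_model` with the PLS model, LDA fit,
#'   selected `n_components`, scaling, and training data.
#' @export
fit_plsda <- function(X, y, max_components = 10, folds = 10, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  # constant columns carry no information and would abort NIPALS
  keep <- colnames(X)[apply(X, 2, stats::var) > 0]
  if (!length(keep)) stop_data("all features have zero variance")
  X <- X[, keep, drop = FALSE]
  cv <- cv_pls_error(X, y, max_components = max_components, folds = folds,
                     seed = seed)
  z <- ztrain(X)
  model <- nipals_pls(z$train, y, cv$n_components)
  ncomp <- min(cv$n_components, model$n_components)
  scores <- pls_scores(model, z$train, ncomp)
  lda_fit <- suppressWarnings(MASS::lda(scores, grouping = factor(y)))
  structure(list(pls = model, lda = lda_fit, n_components = ncomp,
                 features = keep,
                 mu = colMeans(X), sigma = {
                   s <- apply(X, 2, sd); s[s == 0] <- 1; s
                 },
                 cv = cv, X = X, y = y),
            class = "plsda_model")
}

#' Predict faller status (and posterior) for new subjects
#'
#' @param object a `plsda_model` from [fit_plsda()].
#' @param newdata feature matrix on the raw scale.
#' @param ... unused.
#' @return data.frame with `class` (0/1) and `posterior` (probability of
#'   class 1).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    colnames(newdata) <- paste0("f", seq_len(ncol(newdata)))
  }
  newdata <- newdata[, object$features, drop = FALSE]
  Z <- sweep(sweep(newdata, 2, object$mu), 2, object$sigma, "/")
  s <- pls_scores(object$pls, Z, object$n_components)
  post <- predict(object$lda, s)$posterior[, "1"]
  data.frame(class = as.integer(post >= 0.5), posterior = post)
}

#' Target-projection loadings: feature influence ranking
#'
#' The PLS regression vector defines the target-projected component
#' `t_tp = X b / |b|`; each feature's TP loading is the magnitude of its
#' covariance-normalized projection onto that component. Features are
#' ranked descending, ties broken by name.
#'
#' @param model a `plsda_model` (or `pls_model` plus `X`).
#' @param X optional Z-scored feature matrix (defaults to the training data
#'   of a `plsda_model`).
#' @return data.frame `feature`, `tp_loading`, `rank`, `latent_var` (the
#'   component with the largest absolute weight for that feature).
#' @export
tp_loadings <- function(model, X = NULL) {
  if (inherits(model, "plsda_model")) {
    if (is.null(X)) X <- ztrain(model$X)$train
    pls <- model$pls
    ncomp <- model$n_components
  } else {
    pls <- model
    ncomp <- pls$n_components
    if (is.null(X)) stop_config("X required for a bare pls_model")
  }
  b <- pls_coefficients(pls, ncomp)
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop_data("null regression vector; no target projection")
  t_tp <- as.matrix(X) %*% (b / nb)
  p_tp <- abs(drop(crossprod(X, t_tp)) / sum(t_tp^2))
  W <- abs(pls$weights[, seq_len(ncomp), drop = FALSE])
  latent <- apply(W, 1, which.max)
  nm <- pls$feature_names
  if (is.null(nm)) nm <- paste0("f", seq_along(b))
  ord <- order(-p_tp, nm)
  data.frame(feature = nm[ord], tp_loading = p_tp[ord],
             rank = seq_along(ord), latent_var = latent[ord],
             row.names = NULL)
}

#' Backward feature elimination for the PLS-DA model
#'
#' Iteratively removes the feature whose exclusion yields the lowest
#' internal 10-fold cross-validated error (1 - accuracy), down to a single
#' feature, and returns the visited subset with the global minimum error.
#'
#' @param X training feature matrix.
#' @param y 0/1 labels.
#' @param max_components latent-vector search cap.
#' @param folds internal CV folds.
#' @param seed seed controlling fold assignment (fixed across candidate
#'   evaluations for comparability).
#' @return List with `selected` (feature names), `error`, and a `trace`
#'   data.frame (step, removed feature, subset size, error after removal).
#' @export
backward_select <- function(X, y, max_components = 10, folds = 10,
                            seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (ncol(X) < 2) {
    return(list(selected = colnames(X),
                error = cv_pls_error(X, y, max_components, folds, seed)$error,
                trace = data.frame(step = 0L, removed = NA_character_,
                                   n_features = ncol(X),
                                   error = cv_pls_error(X, y, max_components,
                                                        folds, seed)$error)))
  }
  current <- colnames(X)
  best <- list(features = current,
               error = cv_pls_error(X, y, max_components, folds, seed)$error)
  trace <- data.frame(step = 0L, removed = NA_character_,
                      n_features = length(current), error = best$error)
  step <- 0L
  while (length(current) > 1) {
    step <- step + 1L
    errs <- vapply(current, function(f) {
      keep <- setdiff(current, f)
      cv_pls_error(X[, keep, drop = FALSE], y, max_components, folds,
                   seed)$error
    }, numeric(1))
    drop_f <- names(errs)[order(errs, names(errs))][1]
    current <- setdiff(current, drop_f)
    e <- unname(errs[drop_f])
    trace <- rbind(trace, data.frame(step = step, removed = drop_f,
                                     n_features = length(current),
                                     error = e))
    if (e < best$error) best <- list(features = current, error = e)
  }
  list(selected = best$features, error = best$error, trace = trace)
}

confusion_rates <- function(tp, fn, tn, fp) {
  c(accuracy = (tp + tn) / (tp + fn + tn + fp),
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Evaluate a feature set over holdout repetitions
#'
#' For each holdout repetition a PLS-DA model is fitted on the training
#' pairs and applied to the held-out pairs; rates are averaged over
#' repetitions and 95% confidence intervals obtained by a percentile
#' bootstrap over the repetition-level values.
#'
#' @param cohort a [cohort_table()].
#' @param holdouts splits from [make_holdouts()].
#' @param features optional column subset of the cohort features.
#' @param max_components latent-vector search cap.
#' @param n_boot bootstrap resamples for the CIs.
#' @param seed seed for internal CV folds and the bootstrap.
#' @return List of class `performance_report`: `means`, `ci` (2.5/97.5
#'   percentiles), `per_rep` matrix, mean `n_components`, and the pooled
#'   held-out log-likelihood pieces used for AICc.
#' @export
evaluate_plsda <- function(cohort, holdouts, features = NULL,
                           max_components = 10, n_boot = 1000, seed = 1L) {
  X <- cohort$features
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  y <- cohort$subjects$label
  metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  per_rep <- matrix(NA_real_, length(holdouts), length(metrics),
                    dimnames = list(NULL, metrics))
  ncomps <- numeric(length(holdouts))
  loglik <- 0; n_test_total <- 0L
  for (i in seq_along(holdouts)) {
    h <- holdouts[[i]]
    fit <- fit_plsda(X[h$train, , drop = FALSE], y[h$train],
                     max_components = max_components, seed = seed + i)
    pred <- predict(fit, X[h$test, , drop = FALSE])
    yt <- y[h$test]
    tp <- sum(pred$class == 1 & yt == 1); fn <- sum(pred$class == 0 & yt == 1)
    tn <- sum(pred$class == 0 & yt == 0); fp <- sum(pred$class == 1 & yt == 0)
    per_rep[i, ] <- confusion_rates(tp, fn, tn, fp)
    ncomps[i] <- fit$n_components
    pp <- pmin(pmax(pred$posterior, 1e-12), 1 - 1e-12)
    loglik <- loglik + sum(yt * log(pp) + (1 - yt) * log(1 - pp))
    n_test_total <- n_test_total + length(yt)
  }
  means <- colMeans(per_rep, na.rm = TRUE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 77001L)
  boot <- replicate(n_boot, {
    rows <- sample(nrow(per_rep), replace = TRUE)
    colMeans(per_rep[rows, , drop = FALSE], na.rm = TRUE)
  })
  ci <- apply(boot, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  structure(list(means = means, ci = ci, per_rep = per_rep,
                 mean_n_components = mean(ncomps),
                 loglik = loglik, n_obs = n_test_total),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report> mean over", nrow(x$per_rep), "holdouts\n")
  for (m in names(x$means)) {
    cat(sprintf("  %-12s %.3f (%.3f, %.3f)\n", m, x$means[m],
                x$ci[1, m], x$ci[2, m]))
  }
  invisible(x)
}

#' Small-sample corrected AIC for a classifier
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`, with the log-likelihood taken
#' as the binomial likelihood of the held-out labels under the LDA
#' posterior probabilities and `k` the number of latent components plus
#' one. Undefined (flagged `NA`) when `n <= k + 1`.
#'
#' @param loglik binomial log-likelihood on held-out data.
#' @param k parameter count.
#' @param n number of held-out observations.
#' @return AICc value (NA when undefined).
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) return(NA_real_)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare models by AICc and relative likelihood
#'
#' @param reports named list of `performance_report` objects evaluated on
#'   identical holdouts.
#' @return List with a per-model table (`aicc`) and pairwise `delta` /
#'   `rel_likelihood` matrices (`RL = exp((AICc_min - AICc_other)/2)`
#'   entry-wise between pairs); a relative likelihood below 0.05 marks a
#'   significant difference.
#' @export
aicc_compare <- function(reports) {
  tab <- data.frame(model = names(reports),
                    k = vapply(reports, function(r)
                      r$mean_n_components + 1, numeric(1)),
                    loglik = vapply(reports, function(r) r$loglik,
                                    numeric(1)),
                    n = vapply(reports, function(r) r$n_obs, numeric(1)))
  tab$aicc <- mapply(aicc, tab$loglik, tab$k, tab$n)
  m <- length(reports)
  delta <- rl <- matrix(NA_real_, m, m,
                        dimnames = list(names(reports), names(reports)))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      delta[i, j] <- abs(tab$aicc[i] - tab$aicc[j])
      rl[i, j] <- exp((min(tab$aicc[i], tab$aicc[j]) -
                         max(tab$aicc[i], tab$aicc[j])) / 2)
    }
  }
  list(table = tab, delta = delta, rel_likelihood = rl)
}
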