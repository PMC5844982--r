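# Run configuration, seed fan-out, and the end-to-end extraction / report
# orchestration.

#' Assemble a run configuration
#'
#' One serializable list holding every tunable of the pipeline. Unspecified
#' entries take the module defaults.
#'
#' @param seed master seed; per-stage seeds are derived from it (see
#'   [derive_seed()]).
#' @param screen walking-screen settings, see [screen_config()].
#' @param entropy entropy settings, see [entropy_config()].
#' @param epoch_s epoch length in seconds.
#' @param prediction list: `n_reps`, `train_frac`, `max_components`,
#'   `n_boot`.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, screen = screen_config(),
                       entropy = entropy_config(), epoch_s = 30,
                       prediction = list(n_reps = 500, train_frac = 0.8,
                                         max_components = 10,
                                         n_boot = 1000)) {
  structure(list(seed = as.integer(seed), screen = screen,
                 entropy = entropy, epoch_s = epoch_s,
                 prediction = prediction),
            class = "run_config")
}

#' Deterministic per-stage seed derived from the master seed
#'
#' `(seed * 48271 + stage offset) mod (2^31 - 1)`: a fixed multiplicative
#' fan-out so every stage gets a distinct reproducible stream below 2^31.
#'
#' @param seed master seed.
#' @param stage stage name (hashed by character codes) or integer offset.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  off <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    as.integer(stage)
  }
  as.integer((as.numeric(seed) * 48271 + off) %% (2^31 - 1))
}

#' Save / load a run configuration (YAML round-trip)
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `save_config` returns `path` invisibly; `load_config` the
#'   restored `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(seed = raw$seed,
                    screen = utils::modifyList(screen_config(), raw$screen),
                    entropy = utils::modifyList(entropy_config(),
                                                raw$entropy),
                    epoch_s = raw$epoch_s,
                    prediction = raw$prediction)
  # restore numeric vectors yaml may have kept as lists
  for (f in names(cfg$entropy)) {
    if (is.list(cfg$entropy[[f]])) {
      cfg$entropy[[f]] <- unlist(cfg$entropy[[f]])
    }
  }
  for (f in names(cfg$screen)) {
    if (is.list(cfg$screen[[f]])) cfg$screen[[f]] <- unlist(cfg$screen[[f]])
  }
  cfg
}

#' Extract PGME tensors and gait features for a set of recordings
#'
#' Orchestrates the per-subject pipeline: epoch segmentation, walking
#' screen, velocity estimation, step-cycle detection, per-epoch PGME and
#' gait features, and per-subject medians.
#'
#' @param recordings named list (one entry per subject) of either raw bout
#'   matrices (columns AP/ML/V, with an `fs` attribute or `fs` given) or
#'   lists of `simulate_epoch()` results.
#' @param config a [run_config()].
#' @param fs sampling rate for raw bout matrices.
#' @param include_lyapunov include the Lyapunov block of the gait features
#'   (slow; default FALSE for pipeline runs).
#' @param progress print per-subject progress.
#' @return List with `pgme` (named list of subject-level tensors),
#'   `features` (subject x feature matrix of gait features),
#'   `manifest` (per-epoch diagnostics data.frame), and `config`.
#' @export
run_extract <- function(recordings, config = run_config(), fs = 100,
                        include_lyapunov = FALSE, progress = FALSE) {
  if (!length(recordings)) stop_data("no recordings given")
  manifest <- NULL
  tensors <- list()
  feats <- list()
  ecfg <- config$entropy
  for (sid in names(recordings)) {
    rec <- recordings[[sid]]
    epochs <- if (is.list(rec) && !is.null(rec[[1]]$epoch)) {
      lapply(rec, `[[`, "epoch")
    } else {
      segment_epochs(rec, fs = if (!is.null(attr(rec, "fs")))
        attr(rec, "fs") else fs, epoch_s = config$epoch_s, source_id = sid)
    }
    ep_tensors <- list()
    ep_feats <- list()
    for (ei in seq_along(epochs)) {
      ep <- epochs[[ei]]
      scr <- screen_walking(ep, config$screen)
      row <- data.frame(subject = sid, epoch = ei,
                        accepted = scr$accepted, lag = NA_integer_,
                        n_cycles = NA_integer_, error = NA_character_)
      if (scr$accepted) {
        res <- tryCatch({
          vel <- estimate_velocity(ep, n_dirs = ecfg$n_dirs,
                                   max_sift = ecfg$max_sift)
          cyc <- detect_step_cycles(vel)
          tens <- pgme_epoch(ep, cyc, ecfg)
          gf <- gait_feature_vector(ep, cyc,
                                    include_lyapunov = include_lyapunov)
          list(tens = tens, gf = gf, cyc = cyc)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          row$error <- conditionMessage(res)
        } else {
          ep_tensors[[length(ep_tensors) + 1L]] <- res$tens
          ep_feats[[length(ep_feats) + 1L]] <- res$gf
          row$lag <- attr(res$tens, "meta")$lag
          row$n_cycles <- sum(res$cyc$valid)
        }
      }
      manifest <- rbind(manifest, row)
    }
    if (length(ep_tensors)) {
      tensors[[sid]] <- pgme_subject(ep_tensors)
      fm <- do.call(rbind, ep_feats)
      feats[[sid]] <- apply(fm, 2, median, na.rm = TRUE)
    }
    if (progress) message(sid, ": ", length(ep_tensors), " epochs used")
  }
  features <- do.call(rbind, feats)
  list(pgme = tensors, features = features, manifest = manifest,
       config = config)
}

#' Build the three feature subsets for prediction
#'
#' Subset 1: flattened PGME cells; subset 2: conventional gait features plus
#' demographics; subset 3: both combined.
#'
#' @param extract result of [run_extract()].
#' @param subjects subject data.frame (id, label, pair_id, demographics).
#' @param drop_missing drop PGME columns with any missing value.
#' @return Named list of three [cohort_table()] objects (`pgme`, `gait`,
#'   `all`) over the subjects present in the extraction.
#' @export
feature_subsets <- function(extract, subjects, drop_missing = TRUE) {
  ids <- intersect(subjects$id, names(extract$pgme))
  subj <- subjects[match(ids, subjects$id), , drop = FALSE]
  pg <- do.call(rbind, lapply(extract$pgme[ids], pgme_flatten))
  if (drop_missing) {
    pg <- pg[, colSums(is.na(pg)) == 0, drop = FALSE]
  }
  gf <- extract$features[ids, , drop = FALSE]
  demo_cols <- setdiff(names(subj), c("id", "label", "pair_id"))
  demo <- as.matrix(subj[, demo_cols, drop = FALSE])
  gait <- cbind(gf, demo)
  keep_var <- function(m) m[, apply(m, 2, stats::var) > 0, drop = FALSE]
  list(pgme = cohort_table(subj, keep_var(pg)),
       gait = cohort_table(subj, keep_var(gait)),
       all = cohort_table(subj, keep_var(cbind(pg, gait))))
}

#' Human-readable summary of a prediction report
#'
#' @param report list as produced by the CLI `predict` subcommand (or any
#'   list with `performance`, `aicc`, `ranking` entries).
#' @param top number of ranked features to show.
#' @return Invisibly, the lines printed.
#' @export
run_report <- function(report, top = 10) {
  lines <- character()
  emit <- function(...) lines <<- c(lines, sprintf(...))
  if (is.null(report$performance)) stop_config("report lacks 'performance'")
  emit("== Prediction performance ==")
  for (nm in names(report$performance)) {
    p <- report$performance[[nm]]
    emit("%-8s acc %.3f (%.3f-%.3f)  sens %.3f  spec %.3f  ppv %.3f  npv %.3f",
         nm, p$means[["accuracy"]], p$ci[1, "accuracy"], p$ci[2, "accuracy"],
         p$means[["sensitivity"]], p$means[["specificity"]],
         p$means[["ppv"]], p$means[["npv"]])
  }
  if (!is.null(report$aicc)) {
    emit("== AICc comparison (delta, relative likelihood) ==")
    dn <- rownames(report$aicc$delta)
    for (i in seq_along(dn)) for (j in seq_along(dn)) {
      if (i < j) {
        emit("%s vs %s: dAICc %.2f (RL %.3f)", dn[i], dn[j],
             report$aicc$delta[i, j], report$aicc$rel_likelihood[i, j])
      }
    }
  }
  if (!is.null(report$ranking)) {
    emit("== Top %d ranked features (TP loadings) ==", top)
    r <- utils::head(report$ranking, top)
    for (i in seq_len(nrow(r))) {
      emit("%2d. %-28s tp %.4f  LV %d", r$rank[i], r$feature[i],
           r$tp_loading[i], r$latent_var[i])
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
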