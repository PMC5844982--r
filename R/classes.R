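# Light S3 containers for the analysis units.

AXES <- c("AP", "ML", "V")

#' Construct a fixed-length tri-axial acceleration epoch
#'
#' The atomic analysis unit: one window of tri-axial (AP/ML/V) trunk
#' acceleration at a fixed sampling rate. Epochs produced by
#' [segment_epochs()] are 30 s long (3,000 samples at 100 Hz), the window
#' length used for all entropy computations.
#'
#' @param samples numeric matrix, one row per sample, columns `AP`, `ML`, `V`
#'   (reordered by name when named; taken as-is when unnamed).
#' @param fs sampling rate in Hz.
#' @param source_id identifier of the parent recording/bout.
#' @param start_index 0-based sample offset of this epoch in the parent bout.
#' @return An `accel_epoch`: the sample matrix with `fs`, `source_id` and
#'   `start_index` attributes.
#' @export
accel_epoch <- function(samples, fs, source_id = "epoch", start_index = 0L) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) {
    stop_config("an epoch needs exactly the three AP/ML/V channels, got ",
                ncol(samples))
  }
  if (!is.null(colnames(samples))) {
    if (!all(AXES %in% colnames(samples))) {
      stop_config("axis mapping incomplete: need columns ",
                  paste(AXES, collapse = ", "))
    }
    samples <- samples[, AXES, drop = FALSE]
  } else {
    colnames(samples) <- AXES
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_config("fs must be a single positive number")
  }
  check_finite(samples, "acceleration epoch")
  structure(samples, fs = fs, source_id = source_id,
            start_index = as.integer(start_index),
            class = c("accel_epoch", "matrix", "array"))
}

#' @export
print.accel_epoch <- function(x, ...) {
  cat(sprintf("<accel_epoch> %d samples x 3 axes @ %g Hz (%.1f s), source %s\n",
              nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs"),
              attr(x, "source_id")))
  invisible(x)
}

epoch_fs <- function(epoch) attr(epoch, "fs")

epoch_matrix <- function(epoch) {
  m <- unclass(epoch)
  attributes(m) <- list(dim = dim(epoch), dimnames = dimnames(epoch))
  m
}

new_velocity_epoch <- function(samples, fs, detrend_report) {
  structure(samples, fs = fs, detrend_report = detrend_report,
            class = c("velocity_epoch", "matrix", "array"))
}

#' @export
print.velocity_epoch <- function(x, ...) {
  rep <- attr(x, "detrend_report")
  cat(sprintf("<velocity_epoch> %d samples @ %g Hz; removed IMFs per channel: %s\n",
              nrow(x), attr(x, "fs"),
              paste(vapply(rep, function(r) paste(r, collapse = ","), ""),
                    collapse = " | ")))
  invisible(x)
}

new_step_cycles <- function(boundaries, fs, valid_range = c(0.3, 1.0)) {
  boundaries <- as.integer(boundaries)
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop_data("cycle boundaries must be strictly increasing")
  }
  durations <- diff(boundaries)
  dur_s <- durations / fs
  valid <- dur_s >= valid_range[1] & dur_s <= valid_range[2]
  structure(list(boundaries = boundaries, durations = durations,
                 valid = valid, fs = fs),
            class = "step_cycles")
}

#' @export
print.step_cycles <- function(x, ...) {
  cat(sprintf("<step_cycles> %d cycles (%d valid), mean duration %.3f s\n",
              length(x$durations), sum(x$valid),
              mean(x$durations[x$valid]) / x$fs))
  invisible(x)
}

new_phase_windows <- function(index_sets, phases, width) {
  structure(list(index_sets = index_sets, phases = phases, width = width),
            class = "phase_windows")
}

#' @export
print.phase_windows <- function(x, ...) {
  cat("<phase_windows>",
      paste(sprintf("%g%%: %d idx", x$phases,
                    lengths(x$index_sets)), collapse = ", "), "\n")
  invisible(x)
}

new_embedded_pair <- function(X, Y, lag, row_index) {
  structure(list(X = X, Y = Y, lag = as.integer(lag), row_index = row_index),
            class = "embedded_pair")
}

#' @export
print.embedded_pair <- function(x, ...) {
  cat(sprintf("<embedded_pair> %d rows, lag %d (X: 6-dim, Y: 9-dim)\n",
              nrow(x$X), x$lag))
  invisible(x)
}

new_imf_decomposition <- function(imfs, residual, sifts, n_dirs, fs = NULL) {
  structure(list(imfs = imfs, residual = residual, M = length(imfs),
                 meta = list(sifts = sifts, n_dirs = n_dirs), fs = fs),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %d IMFs + residual, %d channels x %d samples\n",
              x$M, ncol(x$residual), nrow(x$residual)))
  invisible(x)
}

new_pgme_tensor <- function(values, level = c("epoch", "subject"),
                            meta = list()) {
  level <- match.arg(level)
  structure(values, level = level, meta = meta,
            class = c("pgme_tensor", "array"))
}

#' @export
print.pgme_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<pgme_tensor level=%s> %d scales x %d phases x %d q (%d missing)\n",
              attr(x, "level"), d[1], d[2], d[3], sum(is.na(x))))
  invisible(x)
}

#' Assemble a cohort table of subjects, labels and features
#'
#' @param subjects data.frame with columns `id`, `label` (0 = non-faller,
#'   1 = faller) and `pair_id` (each pair holds exactly one faller and one
#'   non-faller), plus any demographic columns.
#' @param features numeric subject-by-feature matrix, rows aligned with
#'   `subjects`.
#' @return A `cohort_table` list.
#' @export
cohort_table <- function(subjects, features) {
  stopifnot(is.data.frame(subjects),
            all(c("id", "label", "pair_id") %in% names(subjects)))
  features <- as.matrix(features)
  if (nrow(features) != nrow(subjects)) {
    stop_config("features rows must match subjects rows")
  }
  tab <- table(subjects$pair_id, subjects$label)
  if (!all(tab == 1L)) {
    stop_config("each pair_id must group exactly one faller and one non-faller")
  }
  structure(list(subjects = subjects, features = features),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects (%d fallers), %d features\n",
              nrow(x$subjects), sum(x$subjects$label == 1),
              ncol(x$features)))
  invisible(x)
}
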