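# Epoch segmentation, walking screen, velocity estimation, step cycles and
# phase windows.

#' Cut a walking bout into consecutive 30-s epochs
#'
#' Bouts are split into non-overlapping windows of `epoch_s` seconds from the
#' bout start; a trailing remainder shorter than one window is discarded, and
#' bouts shorter than one window yield no epochs.
#'
#' @param bout matrix or data.frame with columns `AP`, `ML`, `V` (a `time`
#'   column, if present, is ignored for segmentation).
#' @param fs sampling rate in Hz.
#' @param epoch_s epoch duration in seconds (default 30).
#' @param source_id identifier recorded on each epoch.
#' @return List of [accel_epoch()] objects.
#' @export
segment_epochs <- function(bout, fs, epoch_s = 30, source_id = "bout") {
  bout <- as.data.frame(bout)
  if (!all(AXES %in% names(bout))) {
    stop_config("bout must have columns AP, ML, V (missing: ",
                paste(setdiff(AXES, names(bout)), collapse = ", "), ")")
  }
  m <- as.matrix(bout[, AXES])
  check_finite(m, "bout acceleration")
  n <- round(epoch_s * fs)
  k <- floor(nrow(m) / n)
  if (k < 1) return(list())
  lapply(seq_len(k), function(i) {
    accel_epoch(m[((i - 1) * n + 1):(i * n), , drop = FALSE], fs = fs,
                source_id = source_id, start_index = (i - 1L) * n)
  })
}

#' Default parameters of the programmatic walking screen
#'
#' @param band locomotion band (Hz) the dominant spectral peak must fall in.
#' @param prominence minimum ratio of the dominant peak's power to the median
#'   spectral power over the search range.
#' @param search_range frequency range (Hz) searched for the dominant peak.
#' @param window_s,step_s sliding subwindow length and step (s).
#' @param min_fraction fraction of subwindows that must satisfy both criteria.
#' @param peak_tolerance allowed relative deviation of the impact-peak count
#'   from the dominant-frequency-predicted step count.
#' @param enabled set `FALSE` to accept every epoch (screen off).
#' @return Named list of screen parameters.
#' @export
screen_config <- function(band = c(1.2, 3.5), prominence = 4,
                          search_range = c(0.5, 10), window_s = 3,
                          step_s = 1, min_fraction = 0.8,
                          peak_tolerance = 0.3, enabled = TRUE) {
  list(band = band, prominence = prominence, search_range = search_range,
       window_s = window_s, step_s = step_s, min_fraction = min_fraction,
       peak_tolerance = peak_tolerance, enabled = enabled)
}

# raw periodogram of a demeaned, Hamming-windowed segment
periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  x <- (x - mean(x)) * w
  p <- Mod(fft(x))^2 / (n * sum(w^2) / n)
  half <- seq_len(floor(n / 2) + 1)
  list(freq = (half - 1) * fs / n, power = p[half])
}

#' Screen an epoch for walking content
#'
#' Programmatic stand-in for visual epoch inspection. Each sliding subwindow
#' passes when, on the vertical or anterioposterior channel, (a) the dominant
#' spectral peak lies in the locomotion band with sufficient prominence and
#' (b) the number of impact peaks is within `peak_tolerance` of the step
#' count predicted by the dominant frequency. The epoch is accepted when at
#' least `min_fraction` of subwindows pass.
#'
#' @param epoch an [accel_epoch()].
#' @param cfg parameters from [screen_config()].
#' @return List with `accepted` flag and a per-subwindow `report` data.frame.
#' @export
screen_walking <- function(epoch, cfg = screen_config()) {
  fs <- epoch_fs(epoch)
  m <- epoch_matrix(epoch)
  if (isFALSE(cfg$enabled)) {
    return(list(accepted = TRUE,
                report = data.frame(window = integer(), pass = logical())))
  }
  wlen <- round(cfg$window_s * fs)
  step <- round(cfg$step_s * fs)
  starts <- seq(1, nrow(m) - wlen + 1, by = step)
  rows <- lapply(seq_along(starts), function(i) {
    seg <- m[starts[i]:(starts[i] + wlen - 1), , drop = FALSE]
    best <- list(pass = FALSE, f_dom = NA_real_, prom = NA_real_,
                 n_peaks = NA_integer_, spectral_ok = FALSE, peaks_ok = FALSE)
    for (ch in c("V", "AP")) {
      x <- seg[, ch]
      if (stats::var(x) <= 0) next
      pg <- periodogram(x, fs)
      sel <- pg$freq >= cfg$search_range[1] & pg$freq <= cfg$search_range[2]
      if (!any(sel)) next
      pw <- pg$power[sel]; fq <- pg$freq[sel]
      f_dom <- fq[which.max(pw)]
      prom <- max(pw) / max(median(pw), .Machine$double.eps)
      spectral_ok <- f_dom >= cfg$band[1] && f_dom <= cfg$band[2] &&
        prom >= cfg$prominence
      pk <- find_peaks(x - mean(x),
                       min_distance = max(1L, round(0.7 * fs / max(f_dom, 0.5))),
                       min_prominence = 0.8 * sd(x))
      expected <- f_dom * cfg$window_s
      peaks_ok <- abs(length(pk) - expected) <= cfg$peak_tolerance * expected
      if (spectral_ok && peaks_ok) {
        best <- list(pass = TRUE, f_dom = f_dom, prom = prom,
                     n_peaks = length(pk), spectral_ok = TRUE, peaks_ok = TRUE)
        break
      }
      if (is.na(best$f_dom)) {
        best$f_dom <- f_dom; best$prom <- prom; best$n_peaks <- length(pk)
        best$spectral_ok <- spectral_ok; best$peaks_ok <- peaks_ok
      }
    }
    data.frame(window = i, start = starts[i], pass = best$pass,
               f_dom = best$f_dom, prominence = best$prom,
               n_peaks = best$n_peaks, spectral_ok = best$spectral_ok,
               peaks_ok = best$peaks_ok)
  })
  report <- do.call(rbind, rows)
  list(accepted = mean(report$pass) >= cfg$min_fraction, report = report)
}

#' Locate local peaks with a prominence and separation floor
#'
#' @param x numeric vector.
#' @param min_distance minimum separation between kept peaks, in samples.
#' @param min_prominence minimum peak prominence (height above the higher of
#'   the two flanking saddles).
#' @return Integer vector of peak sample indices, increasing.
#' @export
find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer())
  # run-length compression makes flat-topped peaks (plateaus) detectable;
  # the plateau is represented by its central sample
  runs <- rle(x)
  k <- length(runs$values)
  if (k < 3) return(integer())
  starts <- cumsum(c(1L, runs$lengths[-k]))
  v <- runs$values
  peak_runs <- which(v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k]) + 1L
  cand <- starts[peak_runs] + (runs$lengths[peak_runs] - 1L) %/% 2L
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- if (i > 1) x[1:(i - 1)] else h
    higher_l <- which(left > h)
    base_l <- min(left[if (length(higher_l)) (max(higher_l) + 1):(i - 1) else
      seq_along(left)])
    right <- if (i < n) x[(i + 1):n] else h
    higher_r <- which(right > h)
    base_r <- min(right[if (length(higher_r)) 1:(min(higher_r) - 1) else
      seq_along(right)])
    h - max(base_l, base_r)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(integer())
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer()
  for (i in ord) {
    if (!length(sel) || all(abs(sel - i) >= min_distance)) sel <- c(sel, i)
  }
  sort(sel)
}

#' Estimate tri-axial trunk velocity from an acceleration epoch
#'
#' Each channel is demeaned, integrated with the cumulative trapezoid rule,
#' and MEMD-detrended ([detrend_memd()]): the residual trend and all IMFs
#' whose zero-crossing frequency falls below `cutoff_hz` are removed, which
#' suppresses integration drift and inter-stride trends while preserving
#' stride (~1 Hz) and step (~2 Hz) components.
#'
#' @param epoch an [accel_epoch()].
#' @param cutoff_hz zero-crossing-frequency cutoff for IMF removal (Hz).
#' @param n_dirs,max_sift MEMD settings, see [memd()].
#' @return A `velocity_epoch` (matrix with a per-channel `detrend_report`).
#' @export
estimate_velocity <- function(epoch, cutoff_hz = 0.5, n_dirs = 64,
                              max_sift = 15) {
  fs <- epoch_fs(epoch)
  m <- epoch_matrix(epoch)
  if (all(abs(m - mean(m)) < .Machine$double.eps * 4)) {
    stop_data("degenerate epoch: acceleration is constant")
  }
  v <- apply(m, 2, function(a) {
    a <- a - mean(a)
    cumtrapz(a) / fs
  })
  colnames(v) <- AXES
  det <- detrend_memd(v, fs = fs, cutoff_hz = cutoff_hz, n_dirs = n_dirs,
                      max_sift = max_sift)
  out <- det$detrended
  out <- sweep(out, 2, colMeans(out))
  new_velocity_epoch(out, fs = fs, detrend_report = det$removed)
}

cumtrapz <- function(a) {
  n <- length(a)
  c(0, cumsum((a[-n] + a[-1]) / 2))
}

#' Detect step cycles from the vertical velocity
#'
#' The step cycle is taken as the interval between consecutive local extrema
#' of the vertical velocity (minima by default; the maxima convention is
#' available via `extremum`). Extrema must be separated by at least
#' `min_separation_s` and have prominence at least `min_prominence_sd` times
#' the channel SD. Cycles with durations outside `valid_range` (s) are kept
#' but flagged invalid.
#'
#' @param vel a `velocity_epoch` from [estimate_velocity()] (or any matrix
#'   with a `V` column plus an `fs` attribute).
#' @param extremum `"minima"` (default) or `"maxima"`.
#' @param min_separation_s minimum extremum separation (s).
#' @param min_prominence_sd prominence floor in channel-SD units.
#' @param valid_range admissible cycle-duration range (s).
#' @return A `step_cycles` object.
#' @export
detect_step_cycles <- function(vel, extremum = c("minima", "maxima"),
                               min_separation_s = 0.3,
                               min_prominence_sd = 0.1,
                               valid_range = c(0.3, 1.0)) {
  extremum <- match.arg(extremum)
  fs <- attr(vel, "fs")
  v <- vel[, "V"]
  if (sd(v) == 0) stop_data("no gait cycles: vertical velocity is constant")
  x <- if (extremum == "minima") -v else v
  pk <- find_peaks(x, min_distance = round(min_separation_s * fs),
                   min_prominence = min_prominence_sd * sd(v))
  if (length(pk) < 2) stop_data("no gait cycles: fewer than 2 extrema found")
  new_step_cycles(pk, fs = fs, valid_range = valid_range)
}

#' Pool sample indices of step-cycle phase windows
#'
#' For each valid cycle of duration `T` samples and each phase `p` percent,
#' the window covers `floor(width * T)` samples (at least one) starting
#' `round(p * T / 100)` samples after the cycle start. Indices are pooled
#' across cycles per phase.
#'
#' @param cycles a `step_cycles` object.
#' @param phases phase onsets in percent of the step cycle.
#' @param width window width as a fraction of the cycle duration.
#' @return A `phase_windows` object whose `index_sets` are 1-based sample
#'   indices into the parent epoch.
#' @export
phase_windows <- function(cycles, phases = c(0, 20, 40, 60, 80),
                          width = 0.10) {
  if (width <= 0) stop_config("width must be positive")
  if (any(phases < 0 | phases >= 100)) {
    stop_config("phases must lie in [0, 100)")
  }
  keep <- which(cycles$valid)
  if (!length(keep)) stop_data("no valid cycles")
  sets <- lapply(phases, function(p) {
    idx <- lapply(keep, function(i) {
      s <- cycles$boundaries[i]
      d <- cycles$durations[i]
      w <- max(1L, floor(width * d))
      as.integer(s + round(p * d / 100)) + seq_len(w) - 1L
    })
    sort(unique(unlist(idx)))
  })
  names(sets) <- paste0("p", phases)
  new_phase_windows(sets, phases = phases, width = width)
}

#' Read a tri-axial recording from delimited text
#'
#' Expects a header with columns `time`, `AP`, `ML`, `V`; the sampling rate
#' is taken from the median time step unless given.
#'
#' @param path file path (CSV or TSV; the separator is sniffed from the
#'   header line).
#' @param fs sampling rate override (Hz).
#' @return List with `samples` (matrix), `fs`, and `source_id` (file stem).
#' @export
read_recording <- function(path, fs = NULL) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep)
  if (!all(AXES %in% names(df))) {
    stop_config("recording must have columns AP, ML, V: ", path)
  }
  if (is.null(fs)) {
    if (!"time" %in% names(df)) {
      stop_config("no time column and no fs given: ", path)
    }
    fs <- 1 / median(diff(df$time))
  }
  list(samples = as.matrix(df[, AXES]), fs = fs,
       source_id = sub("\\.[^.]*$", "", basename(path)))
}
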