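# Seeded generator of trunk-acceleration-like walking epochs and matched
# faller / non-faller cohorts.

#' Parameters of the synthetic gait generator
#'
#' The generator emulates 30-s tri-axial trunk-acceleration epochs of
#' walking: a Fourier-series gait waveform phase-locked to jittered step
#' cycles (~2 Hz), a damped-oscillation impact transient at each cycle
#' start, and additive Gaussian noise whose SD may vary over step-cycle
#' phase. The faller effect is a phase-localized change of noise SD
#' (default: multiplied by 0.5 in the 60% phase bin, i.e. less irregular
#' trunk acceleration at that phase).
#'
#' @param step_freq mean step frequency (Hz).
#' @param stride_cv fractional SD of the step-interval jitter.
#' @param harmonics 3 x 6 matrix of per-axis amplitudes (m/s^2) of the first
#'   six harmonics of the stride frequency (rows AP, ML, V).
#' @param harmonic_phase 3 x 6 matrix of harmonic phase offsets (rad).
#' @param impact_freq,impact_amp,impact_decay burst frequency (Hz), per-axis
#'   amplitude (m/s^2) and exponential decay constant (s) of the
#'   heel-strike transient at each cycle start.
#' @param noise_sigma baseline noise SD per axis (m/s^2).
#' @param phase_noise_profile multiplicative noise-SD profile over the five
#'   phase bins (0/20/40/60/80%).
#' @param effect_phase,effect_delta phase bin (%) and multiplier applied to
#'   the noise SD in that bin (1 = no effect; the faller default is 0.5 at
#'   60%).
#' @param fs sampling rate (Hz).
#' @param duration epoch duration (s).
#' @return Named list of generator parameters.
#' @export
gait_sim_params <- function(step_freq = 2.0, stride_cv = 0.03,
                            harmonics = NULL, harmonic_phase = NULL,
                            impact_freq = 12, impact_amp = c(0.5, 0.15, 0.8),
                            impact_decay = 0.05, noise_sigma = 0.15,
                            phase_noise_profile = rep(1, 5),
                            effect_phase = 60, effect_delta = 1.0,
                            fs = 100, duration = 30) {
  if (is.null(harmonics)) {
    harmonics <- rbind(AP = c(0.15, 0.80, 0.10, 0.25, 0.05, 0.08),
                       ML = c(0.50, 0.15, 0.10, 0.05, 0.03, 0.02),
                       V  = c(0.10, 1.00, 0.10, 0.30, 0.05, 0.10))
  }
  if (is.null(harmonic_phase)) {
    # V phases are zero so the integrated vertical velocity has an exact
    # minimum at every cycle start: detected and nominal phases coincide
    harmonic_phase <- rbind(AP = c(0.3, 0.0, 1.1, 0.6, 0.2, 1.9),
                            ML = c(0.0, 0.7, 2.1, 1.2, 0.4, 0.9),
                            V  = c(0.0, 0.0, 0.0, 0.0, 0.0, 0.0))
  }
  stopifnot(all(harmonics >= 0), effect_delta > 0, stride_cv >= 0)
  noise_sigma <- rep(noise_sigma, length.out = 3)
  list(step_freq = step_freq, stride_cv = stride_cv, harmonics = harmonics,
       harmonic_phase = harmonic_phase, impact_freq = impact_freq,
       impact_amp = rep(impact_amp, length.out = 3),
       impact_decay = impact_decay, noise_sigma = noise_sigma,
       phase_noise_profile = phase_noise_profile,
       effect_phase = effect_phase, effect_delta = effect_delta,
       fs = fs, duration = duration)
}

#' Simulate one tri-axial walking epoch
#'
#' @param params from [gait_sim_params()].
#' @param seed integer seed; the epoch is a deterministic function of
#'   `(params, seed)`.
#' @param keep_parts return the clean (noise-free) and noise components for
#'   ground-truth checks.
#' @return List with `epoch` (an [accel_epoch()]), `boundaries` (true cycle
#'   start samples, 1-based), and, when `keep_parts`, `clean` and `noise`
#'   matrices.
#' @export
simulate_epoch <- function(params = gait_sim_params(), seed = 1L,
                           keep_parts = FALSE) {
  p <- params
  n <- round(p$duration * p$fs)
  if (n < 2) stop_config("inconsistent fs/duration")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # jittered step intervals covering the epoch, plus slack
  n_guess <- ceiling(p$duration * p$step_freq * 1.5) + 4
  intervals <- (1 / p$step_freq) *
    pmax(0.4, 1 + rnorm(n_guess, 0, p$stride_cv))
  starts_t <- cumsum(c(0, intervals))
  starts_t <- starts_t[starts_t < p$duration]
  n_cyc <- length(starts_t) - 1  # last start opens a truncated cycle
  t <- (seq_len(n) - 1) / p$fs
  # step phase in [0, 1) and cycle index per sample
  cyc <- findInterval(t, starts_t)
  dur_t <- diff(c(starts_t, starts_t[length(starts_t)] +
                    1 / p$step_freq))
  phi <- (t - starts_t[cyc]) / dur_t[cyc]
  phi <- pmin(phi, 0.999999)
  # stride phase: two consecutive step cycles form one stride
  psi <- ((cyc - 1) %% 2 + phi) / 2
  clean <- matrix(0, n, 3, dimnames = list(NULL, AXES))
  for (a in 1:3) {
    for (h in 1:6) {
      clean[, a] <- clean[, a] + p$harmonics[a, h] *
        sin(2 * pi * h * psi + p$harmonic_phase[a, h])
    }
  }
  # damped heel-strike burst at each cycle start
  for (s in starts_t) {
    idx <- which(t >= s & t < s + 6 * p$impact_decay)
    if (!length(idx)) next
    burst <- exp(-(t[idx] - s) / p$impact_decay) *
      sin(2 * pi * p$impact_freq * (t[idx] - s))
    for (a in 1:3) clean[idx, a] <- clean[idx, a] + p$impact_amp[a] * burst
  }
  # phase-dependent noise SD
  bin <- pmin(floor(phi * 5) + 1, 5)
  prof <- p$phase_noise_profile
  eff_bin <- which(c(0, 20, 40, 60, 80) == p$effect_phase)
  if (length(eff_bin)) prof[eff_bin] <- prof[eff_bin] * p$effect_delta
  sd_t <- prof[bin]
  noise <- matrix(rnorm(n * 3), n, 3) * sd_t
  noise <- sweep(noise, 2, p$noise_sigma, "*")
  colnames(noise) <- AXES
  epoch <- accel_epoch(clean + noise, fs = p$fs,
                       source_id = paste0("sim", seed))
  boundaries <- round(starts_t * p$fs) + 1L
  out <- list(epoch = epoch, boundaries = boundaries, n_cycles = n_cyc)
  if (keep_parts) {
    out$clean <- clean
    out$noise <- noise
    out$phase <- phi
  }
  out
}

#' Simulate a matched faller / non-faller cohort
#'
#' Each matched pair shares one set of demographic draws (age, sex, height,
#' weight, walking aid, fall history), mirroring a matched-pair design;
#' subjects get small random effects on step frequency and noise level, and
#' `epochs_per_subject` epochs each.
#'
#' @param n_pairs number of matched pairs.
#' @param faller_params,nonfaller_params [gait_sim_params()] for the two
#'   groups (typically differing in `effect_delta`).
#' @param epochs_per_subject epochs generated per subject.
#' @param seed master seed; all subject/epoch seeds derive from it.
#' @return List with `recordings` (per subject: list of `simulate_epoch()`
#'   results) and `subjects` (data.frame: id, label, pair_id,
#'   demographics).
#' @export
simulate_cohort <- function(n_pairs = 20,
                            faller_params = gait_sim_params(effect_delta = 0.5),
                            nonfaller_params = gait_sim_params(),
                            epochs_per_subject = 10, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  subjects <- NULL
  recordings <- list()
  sid <- 0L
  for (pair in seq_len(n_pairs)) {
    demo <- data.frame(age = round(rnorm(1, 76, 6.7), 1),
                       female = rbinom(1, 1, 0.5),
                       height = round(rnorm(1, 171, 8), 1),
                       weight = round(rnorm(1, 74, 12), 1),
                       walking_aid = rbinom(1, 1, 0.18),
                       fall_history = rbinom(1, 1, 0.4))
    for (label in c(1L, 0L)) {
      sid <- sid + 1L
      base <- if (label == 1L) faller_params else nonfaller_params
      subj <- base
      subj$step_freq <- base$step_freq * exp(rnorm(1, 0, 0.03))
      subj$noise_sigma <- base$noise_sigma * exp(rnorm(1, 0, 0.10))
      id <- sprintf("S%03d", sid)
      epoch_seeds <- sample.int(2^30, epochs_per_subject)
      recordings[[id]] <- lapply(epoch_seeds, function(es) {
        simulate_epoch(subj, seed = es)
      })
      subjects <- rbind(subjects,
                        cbind(data.frame(id = id, label = label,
                                         pair_id = pair), demo))
    }
  }
  list(recordings = recordings, subjects = subjects)
}
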