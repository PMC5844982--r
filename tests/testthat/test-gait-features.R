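sim_with_cycles <- function(seed = 1, duration = 30, ...) {
  sim <- simulate_epoch(quick_params(duration = duration, ...), seed = seed)
  vel <- estimate_velocity(sim$epoch, n_dirs = 8)
  list(epoch = sim$epoch, cycles = detect_step_cycles(vel), sim = sim)
}

test_that("acceleration SDs behave as scale statistics", {
  flat <- accel_epoch(matrix(1, 500, 3), fs = 100)
  expect_true(all(basic_stats(flat)[1:3] == 0))
  set.seed(41)
  ep <- noise_epoch(duration = 20)
  s <- basic_stats(ep)
  expect_true(all(abs(s[1:3] - 1) < 4 / sqrt(2 * 2000)))
  scaled <- accel_epoch(as.matrix(ep) * 2.5, fs = 100)
  expect_equal(unname(basic_stats(scaled)[1:3]), unname(s[1:3] * 2.5),
               tolerance = 1e-12)
})

test_that("stride regularity separates periodic from random signals", {
  sc <- sim_with_cycles(seed = 42, noise_sigma = 0.02, stride_cv = 0.001)
  reg <- stride_regularity(sc$epoch, sc$cycles)
  expect_gt(reg[["regularity_V"]], 0.95)
  expect_gt(reg[["regularity_AP"]], 0.9)
  expect_equal(reg[["stride_time"]], 1.0, tolerance = 0.02)
  expect_equal(reg[["stride_freq"]], 1.0, tolerance = 0.02)
  # white noise at the same cycle bookkeeping: regularity near zero
  set.seed(43)
  noisy <- noise_epoch(duration = 30)
  regn <- stride_regularity(noisy, sc$cycles)
  expect_lt(abs(regn[["regularity_V"]]), 0.1)
  short <- structure(list(boundaries = c(1L, 51L, 101L),
                          durations = c(50L, 50L), valid = rep(TRUE, 2),
                          fs = 100), class = "step_cycles")
  expect_error(stride_regularity(sc$epoch, short),
               class = "pgme_data_error")
})

test_that("stride-time variability is recovered from the simulator", {
  cv <- 0.03
  sds <- vapply(1:30, function(s) {
    sc <- sim_with_cycles(seed = 200 + s, stride_cv = cv)
    stride_regularity(sc$epoch, sc$cycles)[["stride_time_var"]]
  }, numeric(1))
  # stride = 2 steps, each jittered with SD cv/2 s: stride-time SD = cv/2*sqrt(2)
  expect_equal(mean(sds), cv * 0.5 * sqrt(2), tolerance = 0.2)
})

test_that("harmonic ratio follows the even/odd conventions", {
  fs <- 100
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  second <- sin(2 * pi * 2 * t)   # pure 2nd harmonic of 1 Hz stride
  first <- sin(2 * pi * 1 * t)
  ep <- accel_epoch(cbind(AP = second, ML = first, V = second), fs = fs)
  hr <- harmonic_ratio(ep, stride_freq = 1)
  expect_gt(hr[["hr_AP"]], 10)
  expect_gt(hr[["hr_ML"]], 10)   # ML convention inverted: odd / even
  mixed <- accel_epoch(cbind(AP = second + first, ML = second + first,
                             V = second + first), fs = fs)
  hrm <- harmonic_ratio(mixed, stride_freq = 1)
  expect_equal(hrm[["hr_AP"]], 1, tolerance = 0.05)
  expect_equal(hrm[["hr_ML"]], 1, tolerance = 0.05)
})

test_that("index of harmonicity spans its unit range", {
  fs <- 100
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  stride_freq <- 1
  fund_ml <- sin(2 * pi * 1 * t)       # ML fundamental = stride frequency
  fund_apv <- sin(2 * pi * 2 * t)      # AP/V fundamental = step frequency
  ep <- accel_epoch(cbind(AP = fund_apv, ML = fund_ml, V = fund_apv),
                    fs = fs)
  ih <- index_of_harmonicity(ep, stride_freq)
  expect_true(all(ih > 0.97))
  # fundamental absent: power in a higher harmonic only
  ep2 <- accel_epoch(cbind(AP = sin(2 * pi * 6 * t),
                           ML = sin(2 * pi * 3 * t),
                           V = sin(2 * pi * 6 * t)), fs = fs)
  ih2 <- index_of_harmonicity(ep2, stride_freq)
  expect_true(all(ih2 < 0.05))
  # two equal-power lines including the fundamental: close to 1/2
  ep3 <- accel_epoch(cbind(AP = fund_apv + sin(2 * pi * 8 * t),
                           ML = fund_ml + sin(2 * pi * 4 * t),
                           V = fund_apv + sin(2 * pi * 8 * t)), fs = fs)
  ih3 <- index_of_harmonicity(ep3, stride_freq)
  expect_true(all(abs(ih3 - 0.5) < 0.05))
})

test_that("spectral features locate and describe the dominant peak", {
  ep <- tone_epoch(freq = 2, duration = 30, noise = 0.01)
  sp <- spectral_features(ep)
  expect_equal(sp[["dom_freq_AP"]], 2, tolerance = 0.25)
  set.seed(44)
  epn <- noise_epoch(duration = 30)
  spn <- spectral_features(epn)
  # flat spectrum: log-log slope near zero (CI from segment count is wide)
  expect_lt(abs(spn[["slope_V"]]), 0.35)
  # broadband width exceeds the tone's width
  expect_gt(spn[["width_V"]], sp[["width_V"]])
  expect_gt(spn[["range_V"]], sp[["range_V"]])
})

test_that("low-frequency percentage reflects the band split", {
  slow <- tone_epoch(freq = 0.3, duration = 30)
  fast <- tone_epoch(freq = 2, duration = 30)
  expect_gt(low_freq_percentage(slow)[["lfp_AP"]], 90)
  expect_lt(low_freq_percentage(fast)[["lfp_AP"]], 5)
  fs <- 100
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  half <- cbind(AP = sin(2 * pi * 0.3 * t) + sin(2 * pi * 2 * t),
                ML = sin(2 * pi * 0.3 * t) + sin(2 * pi * 2 * t),
                V = sin(2 * pi * 0.3 * t) + sin(2 * pi * 2 * t))
  lf <- low_freq_percentage(accel_epoch(half, fs = fs))
  expect_equal(unname(lf[["lfp_AP"]]), 50, tolerance = 5)
})

test_that("amplitude-invariant features ignore rescaling, SD does not", {
  sc <- sim_with_cycles(seed = 45)
  ep2 <- accel_epoch(as.matrix(sc$epoch) * 3, fs = 100)
  reg1 <- stride_regularity(sc$epoch, sc$cycles)
  reg2 <- stride_regularity(ep2, sc$cycles)
  expect_equal(reg1[["regularity_V"]], reg2[["regularity_V"]],
               tolerance = 1e-9)
  sf <- unname(reg1["stride_freq"])
  expect_equal(harmonic_ratio(sc$epoch, sf), harmonic_ratio(ep2, sf),
               tolerance = 1e-9)
  expect_equal(index_of_harmonicity(sc$epoch, sf),
               index_of_harmonicity(ep2, sf), tolerance = 1e-9)
  expect_equal(low_freq_percentage(sc$epoch), low_freq_percentage(ep2),
               tolerance = 1e-9)
  expect_equal(unname(basic_stats(ep2)[1:3]),
               unname(basic_stats(sc$epoch)[1:3] * 3), tolerance = 1e-12)
})

test_that("a stable limit cycle has a near-zero Lyapunov exponent", {
  t <- seq(0, 20 - 0.01, by = 0.01)
  x <- sin(2 * pi * 2 * t) + 0.001 * rnorm(length(t))
  est <- lyapunov_rosenstein(x, fs = 100, dim = 5, lag = 12, stride_s = 1)
  expect_lt(abs(est$lambda), 0.05)
})

test_that("Rosenstein recovers the Lorenz-63 exponent within 20%", {
  lorenz <- function(t, y, p) {
    list(c(10 * (y[2] - y[1]), y[1] * (28 - y[3]) - y[2],
           y[1] * y[2] - 8 / 3 * y[3]))
  }
  times <- seq(0, 60, by = 0.02)
  sol <- deSolve::ode(c(1, 1, 20), times, lorenz, NULL)
  x <- sol[501:3000, 2]  # past transient; dt = 0.02
  # fit past the initial alignment transient, over the linear region
  est <- lyapunov_rosenstein(x, fs = 50, dim = 3, lag = 5, stride_s = 1,
                             fit_range = c(0.5, 2))
  expect_equal(est$lambda, 0.906, tolerance = 0.20)
})

test_that("noise is dynamically less stable than a tone (both estimators)", {
  set.seed(46)
  t <- seq(0, 10 - 0.01, by = 0.01)
  tone <- sin(2 * pi * 2 * t) + 0.001 * rnorm(length(t))
  noise <- rnorm(length(t))
  for (f in list(lyapunov_rosenstein, lyapunov_wolf)) {
    expect_gt(f(noise, fs = 100, dim = 5, lag = 3)$lambda,
              f(tone, fs = 100, dim = 5, lag = 12)$lambda)
  }
})

test_that("the full feature vector is finite on accepted synthetic epochs", {
  for (s in 1:5) {
    sc <- sim_with_cycles(seed = 500 + s, duration = 15)
    v <- gait_feature_vector(sc$epoch, sc$cycles, include_lyapunov = TRUE)
    expect_true(all(is.finite(v)))
    expect_gt(length(v), 40)
  }
  # broader sweep without the slow Lyapunov block
  for (s in 1:25) {
    sc <- sim_with_cycles(seed = 600 + s, duration = 15)
    v <- gait_feature_vector(sc$epoch, sc$cycles, include_lyapunov = FALSE)
    expect_true(all(is.finite(v)))
  }
})
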