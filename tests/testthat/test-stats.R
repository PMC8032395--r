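test_that("interval statistics implement the CV-Erlang identity", {
  set.seed(1)
  st <- interval_statistics(cumsum(rexp(100, 1)))
  expect_equal(st$cv, st$sd_s / st$mean_s)
  expect_equal(st$erlang_k * st$cv^2, 1)
  # direct evaluations of the stated formula
  expect_equal(1 / 0.43^2, 5.41, tolerance = 1e-3)
  expect_equal(1 / 1^2, 1)
  expect_error(interval_statistics(1), "2 events")
})

test_that("exponential intervals fit a single exponential decay", {
  set.seed(2)
  times <- cumsum(rexp(501, 1 / 0.248))
  st <- suppressWarnings(interval_statistics(times, bin_width = 0.1))
  expect_equal(st$exp_tau_s, 0.248, tolerance = 0.1)
  expect_gt(st$exp_r2, 0.95)
  # the ML gamma cross-check agrees with the CV-based Erlang factor
  iv <- diff(times)
  g <- fit_gamma_ml(iv)
  expect_equal(g$shape, 1 / (stats::sd(iv) / mean(iv))^2, tolerance = 0.2)
})

test_that("Gaussian-interval renewal fits Gaussian better than exponential", {
  prm <- synth_trace_params(duration = 500, dt = 2, unitary_rate = 0,
                            recording_noise_sd = 0, seed = 3)
  st <- interval_statistics(simulate_trace(prm)$events$start_s)
  expect_gt(st$gauss_r2, st$exp_r2)
  expect_gt(st$gauss_r2, 0.7)
  expect_equal(st$gauss_mean_s, 2.34, tolerance = 0.1)
})

test_that("Poisson counts fit the Poisson pmf, quantal counts do not", {
  set.seed(4)
  times <- cumsum(rexp(200, 1)); times <- times[times < 180]
  free <- fit_poisson_counts(times, duration = 180, lambda_constrained = FALSE)
  expect_gt(free$lambda, 0.8); expect_lt(free$lambda, 1.4)
  expect_gt(free$r2, 0.8)
  con <- fit_poisson_counts(times, duration = 180)
  expect_equal(con$lambda, con$mean_count)
  # all-or-none multivesicular quantal rates: bimodal 0 / ~35 per second,
  # constrained fit must fail (negative or near-zero R^2)
  ev <- cumsum(pmax(0.1, rnorm(60, 2.34, 1))); ev <- ev[ev < 180]
  bim <- fit_poisson_counts(ev, duration = 180, weights = rep(35, length(ev)))
  expect_lt(bim$r2, 0.1)
  expect_error(fit_poisson_counts(numeric(0)), "no events")
  expect_error(fit_poisson_counts(c(1, 2), duration = 10), "30 s")
})

test_that("psth pools counts and conserves events", {
  onsets <- c(10, 20, 30)
  ev <- c(onsets + 0.1, onsets + 5)
  h <- psth(ev, onsets, window = c(2, 8), bin = 1)
  expect_equal(sum(h$count), length(ev))
  # all events exactly at onset land in a single bin
  h2 <- psth(onsets + 1e-9, onsets, window = c(2, 8), bin = 1)
  expect_equal(sum(h2$count > 0), 1L)
  expect_equal(max(h2$count), 3L)
  expect_error(psth(numeric(0), onsets), "empty")
})

test_that("event-triggered average recovers a deterministic alignment", {
  t <- seq(0, 100, by = 1e-3)
  stim <- tibble::tibble(time_s = t, voltage_mv = sin(2 * pi * 0.5 * t))
  ev <- seq(10, 90, by = 2) # fixed phase of the 0.5 Hz sinusoid
  eta <- event_triggered_average(stim, ev, pre_window = 1, post_window = 0.5)
  ref <- sin(2 * pi * 0.5 * (ev[1] + eta$lag_s)) - mean(stim$voltage_mv)
  expect_equal(eta$voltage_mv, ref, tolerance = 1e-6)
  expect_error(event_triggered_average(stim, 1000), "usable")
})

test_that("white-noise ETA shows slow depolarisation before events only", {
  prm <- synth_trace_params(duration = 300, dt = 2, unitary_rate = 0,
                            recording_noise_sd = 0, seed = 42)
  sim <- simulate_trace(prm, protocol_white_noise())
  mve <- sim$events$start_s[sim$events$class == "multivesicular"]
  eta <- event_triggered_average(sim$modulation[, c("time_s", "voltage_mv")],
                                 mve)
  pre <- eta$lag_s > -0.8 & eta$lag_s <= 0
  expect_gt(max(eta$voltage_mv[pre]), 5 * mean(eta$se))
  # 20 Hz / 0.7 mV stimulus: terminal filters it out, ETA is noise-like
  sim2 <- simulate_trace(
    synth_trace_params(duration = 300, dt = 2, unitary_rate = 0,
                       recording_noise_sd = 0, seed = 43),
    protocol_white_noise(sd_mv = 0.7, cutoff_hz = 20))
  mve2 <- sim2$events$start_s[sim2$events$class == "multivesicular"]
  eta2 <- event_triggered_average(sim2$modulation[, c("time_s", "voltage_mv")],
                                  mve2)
  expect_lt(mean(abs(eta2$voltage_mv) > 2 * eta2$se), 0.1)
})

test_that("rundown regression and correction reproduce the worked example", {
  # zero-slope data: intercept is the mean
  iv <- rep(2, 20)
  r0 <- suppressWarnings(rundown_regression(iv, seq(0, 9.5, by = 0.5)))
  expect_equal(r0$slope_s_per_min, 0)
  expect_equal(r0$intercept_s, 2)
  expect_error(rundown_regression(iv, rep(1, 20)), "constant")
  expect_error(rundown_regression(1:5, 1:5), "10 intervals")
  # the 35 degrees C correction arithmetic
  rc <- rundown_corrected_interval(1.13, 1.23, 2.26)
  expect_equal(rc$corrected_interval_s, 0.615)
  expect_equal(rc$rate_hz, 1.6)
  expect_equal(rundown_corrected_interval(2, 3, 3)$corrected_interval_s, 2)
  expect_equal(release_rate_hz(1.13 - 0.67), 2.2)
  # paper-style intercept/mean ratio
  expect_equal(1.23 / 2.26, 0.54, tolerance = 0.01)
})
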