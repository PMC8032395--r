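test_that("rate profile implements suppression and rebound", {
  p <- erlang_params()
  expect_equal(rate_profile(c(0, 4.9), p, flash = TRUE), c(2, 2))
  expect_equal(rate_profile(5 + p$T_supp / 2, p, flash = TRUE), 0)
  expect_equal(rate_profile(3, p, flash = FALSE), 2)
  # integrated deficit over the suppression equals R_s * T (the same change
  # as an exponential suppression with time constant T); quadrature check
  tt <- seq(5, 5 + p$T_supp, by = 1e-4)
  deficit <- sum(p$R_s - rate_profile(tt, p, flash = TRUE)) * 1e-4
  expect_equal(deficit, p$R_s * p$T_supp, tolerance = 1e-3)
  # rebound decays from R_s + A back to R_s
  expect_equal(rate_profile(5 + p$T_supp, p, TRUE), p$R_s + p$A)
  expect_equal(rate_profile(10, p, TRUE), p$R_s + p$A * exp(-3.5 / p$tau),
               tolerance = 1e-6)
})

test_that("Erlang sampling yields the configured rate and regularity", {
  # E_f = 1 is the Poisson limit (CV ~ 1); E_f = 6 gives mean 1/R_s and
  # CV = 1/sqrt(6), each within 3 SE of the stationary expectation
  p1 <- erlang_params(E_f = 1)
  iv1 <- pooled_erlang_intervals(p1, 150, 1000)
  cv1 <- stats::sd(iv1) / mean(iv1)
  expect_lt(abs(cv1 - 1), 3 * cv_se(1, length(iv1)))
  p6 <- erlang_params(E_f = 6)
  iv6 <- pooled_erlang_intervals(p6, 150, 2000)
  expect_lt(abs(mean(iv6) - 0.5),
            3 * stats::sd(iv6) / sqrt(length(iv6)))
  expect_lt(abs(stats::sd(iv6) / mean(iv6) - 1 / sqrt(6)),
            3 * cv_se(1 / sqrt(6), length(iv6)))
  # emitted event rate ~ R_s regardless of E_f (thinning by 1/E_f)
  for (ef in c(2, 9)) {
    pe <- erlang_params(E_f = ef)
    n <- mean(vapply(1:100, function(s)
      length(sample_erlang_events(pe, seed = 3000 + s)), numeric(1)))
    expect_equal(n / pe$trial_duration, pe$R_s, tolerance = 0.1)
  }
})

test_that("event-driven and per-bin engines agree", {
  p <- erlang_params(E_f = 4)
  iv_e <- pooled_erlang_intervals(p, 120, 4000)
  iv_b <- unlist(lapply(1:120, function(s)
    diff(sample_erlang_events(p, seed = 5000 + s, engine = "bin"))))
  se_m <- sqrt(stats::sd(iv_e)^2 / length(iv_e) +
                 stats::sd(iv_b)^2 / length(iv_b))
  expect_lt(abs(mean(iv_e) - mean(iv_b)), 3 * se_m)
  cve <- stats::sd(iv_e) / mean(iv_e); cvb <- stats::sd(iv_b) / mean(iv_b)
  expect_lt(abs(cve - cvb),
            3 * sqrt(cv_se(cve, length(iv_e))^2 + cv_se(cvb, length(iv_b))^2))
  # a grid too coarse for the underlying rate is rejected up front
  expect_error(erlang_params(R_s = 20, E_f = 6, dt = 1e-3), "dt")
})

test_that("flash suppression empties the suppression window", {
  p <- erlang_params()
  for (s in 1:50) {
    ev <- sample_erlang_events(p, flash = TRUE, seed = s)
    expect_equal(sum(ev >= 5 & ev < 5 + p$T_supp), 0L)
  }
  # expected count over a flash trial matches the integrated rate
  counts <- vapply(1:300, function(s)
    length(sample_erlang_events(p, flash = TRUE, seed = 6000 + s)), numeric(1))
  expected <- sum(rate_profile(seq(0, 10, 1e-3), p, TRUE)) * 1e-3
  expect_lt(abs(mean(counts) - expected),
            3 * stats::sd(counts) / sqrt(length(counts)))
})

test_that("release responses assemble events, waveform and noise", {
  p <- erlang_params(noise_sd = 0)
  r <- simulate_release_response("erlang", p, flash = FALSE, seed = 2)
  expect_s3_class(r$trace, "tbl_df")
  expect_equal(nrow(r$trace), 10000L)
  # trace is the alpha superposition of the event times
  ref <- alpha_convolve(r$event_times, r$trace$time_s, a = p$alpha_a,
                        tau_r = p$alpha_tau_r)
  expect_equal(r$trace$value, ref)
  expect_error(simulate_release_response("nonsense", p), "arg")
})

test_that("Poisson release model obeys its budget and null suppression", {
  p <- poisson_params(vesicle_rate = 34, noise_sd = 0)
  counts <- vapply(1:200, function(s) {
    length(simulate_release_response("poisson", p, seed = s)$event_times)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 340), 3 * stats::sd(counts) / sqrt(200))
  # suppression_level = 1 means the flash does nothing: flash and null event
  # counts are statistically indistinguishable
  pnull <- poisson_params(suppression_level = 1)
  cf <- vapply(1:120, function(s)
    length(simulate_release_response("poisson", pnull, flash = TRUE,
                                     seed = s)$event_times), numeric(1))
  c0 <- vapply(1:120, function(s)
    length(simulate_release_response("poisson", pnull, flash = FALSE,
                                     seed = 500 + s)$event_times), numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(cf, c0)$p.value), 0.01)
})

test_that("photocurrent model composes photons, thermal events and noise", {
  quiet <- photocurrent_params(thermal_rate = 0, noise_sd_frac = 0)
  r0 <- simulate_photocurrent(0, quiet, seed = 1)
  expect_true(all(r0$trace$value == 0))
  expect_error(simulate_photocurrent(-1, quiet), "negative")
  # ensemble mean tracks f * r_mu at the response peak (law of large numbers)
  f <- 1.5
  tpl <- mvrelease:::photocurrent_templates(quiet)
  pk <- which.max(tpl$r_mu) + round(5 / quiet$dt)
  vals <- vapply(1:400, function(s)
    simulate_photocurrent(f, quiet, seed = s)$trace$value[pk], numeric(1))
  expect_lt(abs(mean(vals) - f * max(tpl$r_mu)),
            3 * stats::sd(vals) / sqrt(length(vals)))
  # variance at the peak grows linearly with flash strength (Poisson sum)
  vals2 <- vapply(1:400, function(s)
    simulate_photocurrent(2 * f, quiet, seed = 800 + s)$trace$value[pk],
    numeric(1))
  expect_equal(stats::var(vals2) / stats::var(vals), 2, tolerance = 0.45)
  # thermal events are Poisson at the configured rate
  p200 <- photocurrent_params(trial_duration = 200, thermal_rate = 0.005,
                              noise_sd_frac = 0)
  nd <- vapply(1:200, function(s)
    length(simulate_photocurrent(0, p200, seed = s)$event_times), numeric(1))
  expect_lt(abs(mean(nd) - 1), 3 * stats::sd(nd) / sqrt(200))
})

test_that("model parameter constructors enforce invariants", {
  expect_error(erlang_params(E_f = 0), "positive integer")
  expect_error(erlang_params(E_f = 2.5), "positive integer")
  expect_error(erlang_params(R_s = 200, dt = 1e-3), "dt")
  expect_error(poisson_params(suppression_level = 2), "suppression_level")
  expect_error(photocurrent_params(thermal_rate = -1), "thermal_rate")
})
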