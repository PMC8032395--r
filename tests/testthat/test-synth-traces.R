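test_that("unitary process is Poisson at the configured rate", {
  # chi-square GOF of per-trace counts against Poisson(lambda = 1/s)
  counts <- vapply(1:20, function(s) {
    prm <- synth_trace_params(duration = 180, dt = 2, unitary_rate = 1,
                              mve_interval_mean = Inf,
                              recording_noise_sd = 0, seed = s)
    nrow(simulate_trace(prm)$events)
  }, numeric(1))
  # counts ~ Poisson(180); normal approximation chi-square
  chi <- sum((counts - 180)^2 / 180)
  p <- stats::pchisq(chi, df = 20, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("silent parameters give a flat, empty recording", {
  prm <- synth_trace_params(duration = 20, unitary_rate = 0,
                            mve_interval_mean = Inf,
                            recording_noise_sd = 0, seed = 1)
  sim <- simulate_trace(prm)
  expect_equal(nrow(sim$events), 0L)
  expect_true(all(sim$trace$current_pA == 0))
  expect_equal(nrow(sim$trace), round(20 * 1000 / prm$dt))
})

test_that("multivesicular intervals match the configured renewal law", {
  pooled <- unlist(lapply(1:20, function(s) {
    prm <- synth_trace_params(duration = 300, dt = 2, unitary_rate = 0,
                              recording_noise_sd = 0, seed = 100 + s)
    diff(simulate_trace(prm)$events$start_s)
  }))
  se <- stats::sd(pooled) / sqrt(length(pooled))
  expect_lt(abs(mean(pooled) - 2.34), 2 * se + 0.02) # 0.02: truncation shift
  expect_equal(stats::sd(pooled) / mean(pooled), 0.43, tolerance = 0.1)
})

test_that("ground truth is exact and reproducible", {
  prm <- synth_trace_params(duration = 60, seed = 7)
  a <- simulate_trace(prm)
  b <- simulate_trace(prm)
  expect_identical(a$trace$current_pA, b$trace$current_pA)
  expect_identical(a$events, b$events)
  # start times strictly increasing; unitary <=> quanta 1
  expect_true(all(diff(a$events$start_s) > 0))
  expect_true(all((a$events$class == "unitary") == (a$events$quanta == 1L)))
  expect_true(all(a$events$quanta >= 1))
})

test_that("single-photon voltage waveform has the stated peak and decay", {
  w <- spr_voltage_waveform(duration = 10, dt = 1)
  expect_equal(min(w$voltage_mv), -3.4)
  expect_equal(w$time_s[which.min(w$voltage_mv)], 0.245, tolerance = 0.005)
  expect_equal(w$voltage_mv[1], 0)
  # log-linear fit to the tail recovers the 2.5 s decay constant
  tail_i <- w$time_s > 2
  fit <- stats::lm(log(-w$voltage_mv[tail_i]) ~ w$time_s[tail_i])
  expect_equal(unname(stats::coef(fit)[2]), -1 / 2.5, tolerance = 0.05)
})

test_that("white-noise stimulus hits its SD and band limit", {
  wn <- white_noise_voltage(sd_mv = 3.5, cutoff_hz = 5, duration = 60,
                            dt = 1, seed = 2)
  expect_equal(stats::sd(wn$voltage_mv), 3.5, tolerance = 0.01)
  # periodogram: power above 2x cutoff < 5% of total
  sp <- stats::spec.pgram(stats::ts(wn$voltage_mv, frequency = 1000),
                          plot = FALSE, taper = 0)
  hi <- sp$freq > 10
  expect_lt(sum(sp$spec[hi]) / sum(sp$spec), 0.05)
  # zero request gives zeros; super-Nyquist cutoff errors
  expect_true(all(white_noise_voltage(0, 5, 1, 1)$voltage_mv == 0))
  expect_error(white_noise_voltage(1, 600, 1, 1), "Nyquist")
})

test_that("hyperpolarising step lengthens intervals to the stepped mean", {
  post <- unlist(lapply(1:20, function(s) {
    prm <- synth_trace_params(duration = 90, dt = 2, unitary_rate = 0,
                              mve_interval_mean = 2.405,
                              mve_interval_cv = 1.430 / 2.405,
                              recording_noise_sd = 0, seed = s)
    sim <- simulate_trace(prm, protocol_step(onset_s = 30))
    diff(sim$events$start_s[sim$events$start_s > 31])
  }))
  se <- stats::sd(post) / sqrt(length(post))
  expect_lt(abs(mean(post) - 3.744), 2 * se + 0.05)
})

test_that("constant protocol leaves the modulation flat", {
  mod <- modulate_rates(list(mean = 2.34, sd = 1), protocol_constant(),
                        duration = 10, dt = 1)
  expect_true(all(mod$intensity_rel == 1))
  expect_true(all(mod$interval_mean == 2.34))
})

test_that("single-photon waveform suppresses release and rebounds after", {
  onsets <- seq(5, by = 10, length.out = 20)
  evs <- unlist(lapply(1:10, function(s) {
    prm <- synth_trace_params(duration = 205, dt = 2, unitary_rate = 0,
                              recording_noise_sd = 0, seed = 100 + s)
    sim <- simulate_trace(prm, protocol_spr(onsets = onsets))
    sim$events$start_s[sim$events$class == "multivesicular"]
  }))
  h <- psth(evs, onsets, window = c(2, 8), bin = 0.25)
  base <- mean(h$count[h$bin_mid_s < 0])
  during <- mean(h$count[h$bin_mid_s > 0 & h$bin_mid_s < 1.5])
  after <- mean(h$count[h$bin_mid_s > 3 & h$bin_mid_s < 4])
  expect_lt(during, 0.1 * base)
  expect_gt(after / base, 1.5 * 0.8)
  expect_lt(after / base, 1.5 * 1.2)
})

test_that("interval distributions mirror the -70 vs -40 mV statistics", {
  # unitary (Poisson) intervals pass a KS test against the exponential law;
  # the CV=0.43 multivesicular renewal fails it
  uni <- unlist(lapply(1:5, function(s) {
    prm <- synth_trace_params(duration = 200, dt = 2, unitary_rate = 1,
                              mve_interval_mean = Inf,
                              recording_noise_sd = 0, seed = 200 + s)
    diff(simulate_trace(prm)$events$start_s)
  }))
  mve <- unlist(lapply(1:5, function(s) {
    prm <- synth_trace_params(duration = 400, dt = 2, unitary_rate = 0,
                              recording_noise_sd = 0, seed = 300 + s)
    diff(simulate_trace(prm)$events$start_s)
  }))
  # intervals sit on the simulation grid; dither below grid resolution to
  # remove ties before the KS test
  set.seed(1)
  uni <- uni + stats::runif(length(uni), 0, 2e-3)
  mve <- mve + stats::runif(length(mve), 0, 2e-3)
  expect_gt(stats::ks.test(uni, "pexp", 1 / mean(uni))$p.value, 0.01)
  expect_lt(stats::ks.test(mve, "pexp", 1 / mean(mve))$p.value, 0.01)
})

test_that("rundown slope is recovered from a 10-minute recording", {
  ests <- vapply(1:8, function(s) {
    prm <- synth_trace_params(duration = 600, dt = 2, unitary_rate = 0,
                              rundown_interval_slope = 0.33,
                              recording_noise_sd = 0, seed = 400 + s)
    ev <- simulate_trace(prm)$events$start_s
    iv <- diff(ev)
    unlist(rundown_regression(iv, ev[-1] / 60))[1:2]
  }, numeric(2))
  slope <- ests[2, ]
  se <- stats::sd(slope) / sqrt(length(slope))
  expect_lt(abs(mean(slope) - 0.33), 2 * se + 0.02)
})

test_that("parameter validation rejects impossible configurations", {
  expect_error(synth_trace_params(duration = -1), "duration")
  expect_error(synth_trace_params(mve_interval_cv = 1.5), "cv")
  expect_error(synth_trace_params(unitary_rate = -2), "unitary_rate")
})
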