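test_that("difference-of-means discriminant matches analytic d-prime", {
  set.seed(1)
  n <- 2000; d <- 50
  delta <- rep(0.5, d)
  flash <- matrix(stats::rnorm(n * d, 0, 1), n) + rep(delta, each = n)
  null <- matrix(stats::rnorm(n * d, 0, 1), n)
  m <- train_discriminant(flash, null)
  # D converges on delta; projection d-prime on |delta| for unit noise
  expect_equal(mean(m$D), 0.5, tolerance = 0.05)
  dp <- glance(m)$d_prime
  expect_equal(dp, sqrt(sum(delta^2)), tolerance = 0.05)
  # identical ensembles give a zero discriminant
  same <- matrix(stats::rnorm(500 * d), 500)
  m0 <- train_discriminant(same, same)
  expect_equal(max(abs(m0$D)), 0, tolerance = 1e-12)
  expect_error(train_discriminant(flash, null[, 1:10]), "same length")
})

test_that("Bayesian pooling follows the stated weight algebra", {
  m <- structure(list(D = rep(1, 4), mu_A = 2, sigma_A = 1, mu_B = 0,
                      sigma_B = 1, center = 1, n_train = 10),
                 class = "discriminant_model")
  # f = 0: Pois(1|0)/Pois(0|0) = 0, so every weight and the pool are zero
  expect_equal(pooled_response(NULL, m, f = 0, projections = c(-3, 5)), 0)
  # symmetric case mu_A = mu_B: likelihood ratio 1, weights equal f
  ms <- m; ms$mu_A <- ms$mu_B <- 0; ms$center <- 0
  f <- 0.3; p <- c(1, 2, -1)
  expect_equal(pooled_response(NULL, ms, f, projections = p), f * sum(p))
  # weights are monotone in the projection: a flash-like rod dominates
  w <- mvrelease:::observer_weights(c(0, 2, 6), m, f = 0.5)
  expect_true(all(diff(w) > 0))
  # extreme projections stay finite through the log-space cap
  expect_true(is.finite(pooled_response(NULL, m, 1, projections = 1e6)))
  mzero <- m; mzero$sigma_A <- 0
  expect_error(pooled_response(NULL, mzero, 1, projections = 1), "sigma")
})

test_that("ideal photon detector has its closed form and threshold", {
  expect_equal(ideal_photon_detector(24, 0), 0.5)
  expect_equal(ideal_photon_detector(24, 1e6), 1)
  expect_equal(ideal_photon_detector(24, log(2) / 24), 0.75)
  expect_equal(log(2) / 24, 0.0289, tolerance = 1e-3)
  expect_error(ideal_photon_detector(-1, 0.1), ">= 0")
})

test_that("psychometric fitting recovers exact cumulative-Gaussian data", {
  s <- 10^seq(-3, 0, length.out = 9)
  fc <- 0.5 + 0.5 * stats::pnorm((log10(s) + 1.2) / 0.4)
  fit <- fit_psychometric(tibble::tibble(flash_strength = s,
                                         fraction_correct = fc))
  expect_equal(fit$m, -1.2, tolerance = 1e-3)
  expect_equal(fit$sd, 0.4, tolerance = 1e-3)
  expect_equal(fit$threshold_75, 10^-1.2, tolerance = 1e-3)
  expect_false(fit$extrapolated)
  # ideal-detector fractions give the closed-form threshold ln2/24
  fi <- fit_psychometric(tibble::tibble(
    flash_strength = s, fraction_correct = ideal_photon_detector(24, s)))
  expect_equal(fi$threshold_75, log(2) / 24, tolerance = 0.15)
  expect_error(fit_psychometric(tibble::tibble(flash_strength = 1:2,
                                               fraction_correct = c(.5, 1))),
               "4 flash strengths")
})

test_that("an uninformative generator performs at chance", {
  # zero suppression and rebound: flash trials carry no signal
  p <- erlang_params(T_supp = 0, A = 0)
  res <- run_2afc("erlang", p, n_rods = 12,
                  flash_strengths = c(0.01, 0.1, 1), n_trials = 200, seed = 3)
  for (i in seq_len(nrow(res))) {
    expect_lt(abs(res$fraction_correct[i] - 0.5), 3 * res$se[i] + 1e-9)
  }
})

test_that("2AFC runs are deterministic and broadly monotone", {
  p <- erlang_params()
  fs <- 10^seq(-3, 0, length.out = 6)
  a <- run_2afc("erlang", p, n_rods = 24, flash_strengths = fs,
                n_trials = 100, seed = 11)
  b <- run_2afc("erlang", p, n_rods = 24, flash_strengths = fs,
                n_trials = 100, seed = 11)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  # psychometric curve rises from chance to near-perfect
  expect_lt(a$fraction_correct[1], 0.65)
  expect_gt(a$fraction_correct[6], 0.95)
  # isotonic violations no larger than sampling noise
  viol <- -diff(a$fraction_correct)
  expect_true(all(viol < 3 * sqrt(2) * max(a$se)))
  # the ideal detector upper-bounds the model at every strength
  ideal <- ideal_photon_detector(24, fs)
  se_floor <- pmax(a$se, sqrt(ideal * (1 - ideal) / a$n_trials), 1e-3)
  expect_true(all(a$fraction_correct <= ideal + 3 * se_floor))
})

test_that("Bayesian weighting beats unweighted pooling", {
  p <- erlang_params()
  fs <- 10^seq(-3, 0, length.out = 5)
  wb <- run_2afc("erlang", p, n_rods = 24, flash_strengths = fs,
                 n_trials = 150, seed = 7)
  wu <- run_2afc("erlang", p, n_rods = 24, flash_strengths = fs,
                 n_trials = 150, seed = 7, weighting = "unweighted")
  se2 <- sqrt(wb$se^2 + wu$se^2)
  expect_true(all(wb$fraction_correct >= wu$fraction_correct - 3 * se2))
  expect_gt(mean(wb$fraction_correct - wu$fraction_correct), 0)
})

test_that("small trial counts are flagged as noisy", {
  p <- erlang_params()
  expect_warning(
    res <- run_2afc("erlang", p, n_rods = 4, flash_strengths = c(0.05, 0.5),
                    n_trials = 20, seed = 1),
    "noisy")
  expect_true(attr(res, "noisy"))
})
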