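#' Train a difference-of-means linear discriminant
#'
#' Constructs the ideal observer's linear stage from training ensembles:
#' `D = mean(flash) - mean(null)`, and summarises the projections of each
#' class onto `D` by their means and standard deviations (`mu_A`, `sigma_A`
#' for flash; `mu_B`, `sigma_B` for null).
#'
#' @param flash_responses,null_responses numeric matrices (trials x time
#'   samples) of simulated responses; equal numbers of columns required.
#' @return A list of class `discriminant_model`: `D`, `mu_A`, `sigma_A`,
#'   `mu_B`, `sigma_B`, `n_train`.
#' @export
train_discriminant <- function(flash_responses, null_responses) {
  flash_responses <- as.matrix(flash_responses)
  null_responses <- as.matrix(null_responses)
  if (ncol(flash_responses) != ncol(null_responses))
    stop("flash and null responses must have the same length", call. = FALSE)
  if (nrow(flash_responses) < 2L || nrow(null_responses) < 2L)
    stop("need >= 2 responses per class", call. = FALSE)
  D <- colMeans(flash_responses) - colMeans(null_responses)
  pA <- as.numeric(flash_responses %*% D)
  pB <- as.numeric(null_responses %*% D)
  new_discriminant(D, pA, pB,
                   n_train = min(nrow(flash_responses), nrow(null_responses)))
}

new_discriminant <- function(D, pA, pB, n_train) {
  structure(list(D = D, mu_A = mean(pA), sigma_A = stats::sd(pA),
                 mu_B = mean(pB), sigma_B = stats::sd(pB),
                 center = (mean(pA) + mean(pB)) / 2,
                 n_train = n_train),
            class = "discriminant_model")
}

# internal: Bayes-optimal nonlinear weights for projections p at prior
# strength f. Gaussian likelihood ratio computed in log space and capped at
# e^+/-50; the Poisson prior Pois(1|f)/Pois(0|f) = f multiplies afterwards so
# f = 0 gives exactly zero weights.
observer_weights <- function(p, model, f) {
  if (model$sigma_A <= 0 || model$sigma_B <= 0)
    stop("zero sigma in discriminant model", call. = FALSE)
  lr <- stats::dnorm(p, model$mu_A, model$sigma_A, log = TRUE) -
    stats::dnorm(p, model$mu_B, model$sigma_B, log = TRUE)
  exp(pmin(pmax(lr, -50), 50)) * f
}

#' Pooled observer response over a population of rods
#'
#' Projects each rod's response onto the trained discriminant and combines
#' them with the Bayes-optimal nonlinear weighting
#' `w_i = G(p_i | mu_A, sigma_A) P(1|f) / (G(p_i | mu_B, sigma_B) P(0|f))`,
#' returning `R = sum_i w_i p_i`, with projections centred at the midpoint of
#' the two training classes so that flash-consistent rods always push `R`
#' upward regardless of the raw projection sign. The weighting approximates
#' the nonlinear thresholding at the rod to rod-bipolar synapse. Weights are
#' computed in log space with the likelihood ratio capped at `e^{+/-50}` so
#' `R` is finite for any finite projection.
#'
#' @param rod_responses numeric matrix (rods x time samples), or `NULL` if
#'   `projections` is supplied.
#' @param model a trained [train_discriminant()] model.
#' @param f flash strength acting as the Poisson prior (Rh*/rod).
#' @param projections optional precomputed projections `r_i . D`.
#' @return The pooled scalar response `R`.
#' @export
pooled_response <- function(rod_responses, model, f, projections = NULL) {
  stopifnot(inherits(model, "discriminant_model"))
  p <- projections %||% as.numeric(as.matrix(rod_responses) %*% model$D)
  ctr <- model$center %||% 0
  sum(observer_weights(p, model, f) * (p - ctr))
}

#' Ideal photon detector performance
#'
#' The optimal detector limited only by Poisson fluctuations in photon
#' absorption: it is correct whenever at least one photon is absorbed in the
#' pool and guesses otherwise, so
#' `FC = 1 - 0.5 * exp(-n_rods * flash_strength)`. Its 75%-correct threshold
#' is `log(2) / n_rods`.
#'
#' @param n_rods rods in the pool, >= 0.
#' @param flash_strength flash strength (Rh*/rod), >= 0; vectorised.
#' @return Fraction correct in `[0.5, 1]`.
#' @export
#' @examples
#' ideal_photon_detector(24, log(2) / 24) # 0.75
ideal_photon_detector <- function(n_rods, flash_strength) {
  if (any(n_rods < 0) || any(flash_strength < 0))
    stop("inputs must be >= 0", call. = FALSE)
  1 - 0.5 * exp(-n_rods * flash_strength)
}

# ---------------------------------------------------------------------------
# projection context: everything needed to draw `response . D` for one rod
# without materialising the response, exact because projection is linear.

# cross-correlation of a kernel with D: g[j] = sum_m K[m] * D[j + m - 1],
# i.e. the projection contributed by one event whose onset falls in bin j
event_projection_kernel <- function(D, kern) {
  n <- length(D)
  m <- length(kern)
  N <- stats::nextn(n + m, 2)
  Dp <- c(D, numeric(N - n))
  Kp <- c(kern, numeric(N - m))
  g <- Re(stats::fft(stats::fft(Dp) * Conj(stats::fft(Kp)), inverse = TRUE)) / N
  g[seq_len(n)]
}

# mean response of a release-model class from n_train simulated event trains
release_training_mean <- function(sampler, n_train, grid, a, tau_r, noise_sd) {
  n <- length(grid)
  dt <- grid[2] - grid[1]
  hist_counts <- numeric(n)
  lists <- vector("list", n_train)
  for (i in seq_len(n_train)) {
    ev <- sampler()
    lists[[i]] <- ev
    if (length(ev)) {
      idx <- pmin(n, pmax(1L, round(ev / dt) + 1L))
      hist_counts[idx] <- hist_counts[idx] + 1
    }
  }
  klen <- min(n, ceiling(10 * tau_r / dt))
  kern <- alpha_waveform(seq_len(klen) * dt - dt, a = a, tau_r = tau_r)
  full <- stats::convolve(hist_counts / n_train, rev(kern), type = "open")
  mu <- full[seq_len(n)]
  # the zero-mean recording noise survives in a finite-ensemble mean
  if (noise_sd > 0) mu <- mu + stats::rnorm(n, 0, noise_sd / sqrt(n_train))
  list(mean = mu, event_lists = lists)
}

# build the observer context for a release model (erlang | poisson)
release_observer_context <- function(model, params, n_train, grid_dt) {
  dur <- params$trial_duration
  grid <- seq(0, dur - grid_dt, by = grid_dt)
  n <- length(grid)
  sample_flash <- if (model == "erlang") {
    function() sample_erlang_events(params, flash = TRUE)
  } else {
    function() sample_poisson_events(params, flash = TRUE)
  }
  sample_null <- if (model == "erlang") {
    function() sample_erlang_events(params, flash = FALSE)
  } else {
    function() sample_poisson_events(params, flash = FALSE)
  }
  trF <- release_training_mean(sample_flash, n_train, grid,
                               params$alpha_a, params$alpha_tau_r,
                               params$noise_sd)
  trN <- release_training_mean(sample_null, n_train, grid,
                               params$alpha_a, params$alpha_tau_r,
                               params$noise_sd)
  D <- trF$mean - trN$mean
  klen <- min(n, ceiling(10 * params$alpha_tau_r / grid_dt))
  kern <- alpha_waveform(seq_len(klen) * grid_dt - grid_dt,
                         a = params$alpha_a, tau_r = params$alpha_tau_r)
  g <- event_projection_kernel(D, kern)
  sigma_proj <- params$noise_sd * sqrt(sum(D^2))
  proj_of <- function(ev) {
    if (length(ev) == 0L) return(0)
    sum(g[pmin(n, pmax(1L, round(ev / grid_dt) + 1L))])
  }
  pA <- vapply(trF$event_lists, proj_of, numeric(1)) +
    stats::rnorm(n_train, 0, sigma_proj)
  pB <- vapply(trN$event_lists, proj_of, numeric(1)) +
    stats::rnorm(n_train, 0, sigma_proj)
  disc <- new_discriminant(D, pA, pB, n_train)
  draw <- function(K, flash) {
    smp <- if (flash) sample_flash else sample_null
    ev_sum <- vapply(seq_len(K), function(i) proj_of(smp()), numeric(1))
    ev_sum + stats::rnorm(K, 0, sigma_proj)
  }
  list(model = model, params = params, disc = disc, grid_dt = grid_dt,
       draw_null = function(K) draw(K, FALSE),
       draw_flash = function(K, photons = rep(1L, K)) draw(K, TRUE))
}

# build the observer context for the photocurrent model
photocurrent_observer_context <- function(params, n_train, grid_dt) {
  tpl <- photocurrent_templates(params)
  n <- length(tpl$t)
  dt <- params$dt
  sds <- tpl$w_sds * params$spr_variability_scale
  noise_sd <- params$noise_sd_frac / 1.22 * params$noise_scale
  a_lp <- exp(-2 * pi * params$noise_cutoff_hz * dt)
  f_idx <- round(params$flash_time / dt) + 1L
  shift_tail <- function(v, i0) c(numeric(i0 - 1L), v[1:(n - i0 + 1L)])
  r_mu_f <- shift_tail(tpl$r_mu, f_idx)
  c1_f <- shift_tail(tpl$c1, f_idx)
  c2_f <- shift_tail(tpl$c2, f_idx)
  thermal_rate <- params$thermal_rate
  dur <- params$trial_duration
  # D = mean(flash) - mean(null) over an n_train-trial training set: thermal
  # and noise terms are common to both classes and cancel in expectation;
  # the finite-ensemble residue of each stochastic term is retained, as it
  # would be in a fully simulated training set.
  mean_flash <- r_mu_f +
    stats::rnorm(n, 0, sds[1] / sqrt(n_train)) * c1_f +
    stats::rnorm(n, 0, sds[2] / sqrt(n_train)) * c2_f +
    stats::rnorm(n, 0, 2 * noise_sd / sqrt(n_train))
  D <- mean_flash
  g_mu <- event_projection_kernel(D, tpl$r_mu)
  g_c1 <- event_projection_kernel(D, tpl$c1)
  g_c2 <- event_projection_kernel(D, tpl$c2)
  rmuD <- sum(r_mu_f * D); c1D <- sum(c1_f * D); c2D <- sum(c2_f * D)
  # exact projection SD of the stationary AR(1)-filtered continuous noise:
  # eta . D = z . corr(h, D) for unit white z and impulse response h scaled
  # to the stationary SD
  hlen <- min(n, ceiling(log(1e-10) / log(a_lp)))
  sd_stat <- (1 - a_lp) / sqrt(1 - a_lp^2)
  hN <- (1 - a_lp) * a_lp^(0:(hlen - 1L)) * (noise_sd / sd_stat)
  gh <- event_projection_kernel(D, hN)
  sigma_noise_proj <- sqrt(sum(gh^2))
  thermal_proj <- function(K) {
    out <- numeric(K)
    Nd <- stats::rpois(K, thermal_rate * dur)
    hit <- which(Nd > 0)
    for (i in hit) {
      td <- stats::runif(Nd[i], 0, dur)
      idx <- pmin(n, round(td / dt) + 1L)
      out[i] <- sum(g_mu[idx]) +
        sum(stats::rnorm(Nd[i], 0, sds[1]) * g_c1[idx]) +
        sum(stats::rnorm(Nd[i], 0, sds[2]) * g_c2[idx])
    }
    out
  }
  draw <- function(K, photons) {
    base <- photons * rmuD +
      stats::rnorm(K, 0, sqrt(pmax(photons, 0)) * sds[1]) * c1D +
      stats::rnorm(K, 0, sqrt(pmax(photons, 0)) * sds[2]) * c2D
    base + thermal_proj(K) + stats::rnorm(K, 0, sigma_noise_proj)
  }
  pA <- draw(n_train, rep(1L, n_train))
  pB <- draw(n_train, rep(0L, n_train))
  disc <- new_discriminant(D, pA, pB, n_train)
  list(model = "photocurrent", params = params, disc = disc, grid_dt = dt,
       draw_null = function(K) draw(K, rep(0L, K)),
       draw_flash = function(K, photons = rep(1L, K)) draw(K, photons))
}

build_observer_context <- function(model, params, n_train, grid_dt) {
  switch(model,
         erlang = ,
         poisson = release_observer_context(model, params, n_train, grid_dt),
         photocurrent = photocurrent_observer_context(params, n_train, grid_dt),
         stop("invalid model id: ", model, call. = FALSE))
}

#' Run the two-alternative forced-choice detection task
#'
#' Simulates the full ideal-observer experiment: a difference-of-means
#' discriminant is trained on 1000 single-photon (exactly 1 Rh*, no Poisson
#' fluctuation) and 1000 null responses, then at each test flash strength
#' pairs of pooled responses (flash vs null, `n_rods` rods each) are compared
#' over `n_trials` trials. Test flash responses include Poisson fluctuations
#' in the photon count per rod. A trial is correct when the flash pool's
#' pooled response exceeds the null pool's; exact ties score correct with 50%
#' probability.
#'
#' @param model `"erlang"`, `"poisson"`, or `"photocurrent"`.
#' @param params matching parameter object ([erlang_params()],
#'   [poisson_params()], [photocurrent_params()]).
#' @param n_rods rods in the pool (default 24).
#' @param flash_strengths test strengths (Rh*/rod); default 12 log-spaced
#'   points over 0.001-1.0.
#' @param n_trials trials per strength (default 400); below 50 a `noisy`
#'   flag is set.
#' @param seed integer master seed.
#' @param n_train training responses per class (default 1000).
#' @param grid_dt response sample interval for the observer (s).
#' @param weighting `"bayes"` (Eq. weights) or `"unweighted"`
#'   (`R = sum p_i`), for comparison.
#' @return A tibble of class `psychometric_result` with columns
#'   `flash_strength`, `n_trials`, `n_correct`, `fraction_correct`, `se`
#'   (binomial), and attributes `model`, `n_rods`, `seed`, `noisy`.
#' @export
run_2afc <- function(model = c("erlang", "poisson", "photocurrent"), params,
                     n_rods = 24,
                     flash_strengths = 10^seq(-3, 0, length.out = 12),
                     n_trials = 400, seed = 1L, n_train = 1000,
                     grid_dt = 1e-3, weighting = c("bayes", "unweighted")) {
  model <- match.arg(model)
  weighting <- match.arg(weighting)
  noisy <- n_trials < 50
  if (noisy) warning("n_trials < 50: noisy psychometric estimate",
                     call. = FALSE)
  set.seed(derive_seed(seed, 0L))
  ctx <- build_observer_context(model, params, n_train, grid_dt)
  disc <- ctx$disc
  res <- vector("list", length(flash_strengths))
  for (si in seq_along(flash_strengths)) {
    f <- flash_strengths[si]
    set.seed(derive_seed(seed, si))
    K <- n_trials * n_rods
    photons <- stats::rpois(K, f)
    p_flash <- numeric(K)
    idx_on <- which(photons >= 1L)
    if (length(idx_on))
      p_flash[idx_on] <- ctx$draw_flash(length(idx_on), photons[idx_on])
    if (length(idx_on) < K)
      p_flash[-idx_on] <- if (length(idx_on)) ctx$draw_null(K - length(idx_on)) else ctx$draw_null(K)
    p_null <- ctx$draw_null(K)
    pf <- matrix(p_flash, nrow = n_trials)
    pn <- matrix(p_null, nrow = n_trials)
    if (weighting == "bayes") {
      Rf <- rowSums(observer_weights(pf, disc, f) * (pf - disc$center))
      R0 <- rowSums(observer_weights(pn, disc, f) * (pn - disc$center))
    } else {
      Rf <- rowSums(pf)
      R0 <- rowSums(pn)
    }
    correct <- Rf > R0
    ties <- Rf == R0
    if (any(ties)) correct[ties] <- stats::runif(sum(ties)) < 0.5
    res[[si]] <- tibble::tibble(flash_strength = f, n_trials = n_trials,
                                n_correct = sum(correct),
                                fraction_correct = mean(correct))
  }
  out <- dplyr::bind_rows(res)
  out$se <- sqrt(out$fraction_correct * (1 - out$fraction_correct) /
                   out$n_trials)
  structure(out,
            class = c("psychometric_result", class(tibble::tibble())),
            model = model, n_rods = n_rods, seed = seed, noisy = noisy,
            weighting = weighting, discriminant = disc)
}

#' Fit a cumulative Gaussian psychometric function
#'
#' Fits `FC(s) = 0.5 + 0.5 * Phi((log10(s) - m) / sd)` to the observed
#' fractions correct by least squares and extracts the 75%-correct threshold,
#' which for this parameterisation is exactly `10^m`.
#'
#' @param result a `psychometric_result` from [run_2afc()], or any data frame
#'   with `flash_strength` and `fraction_correct` columns.
#' @return A list of class `psychometric_fit`: `m`, `sd`, `threshold_75`,
#'   `extrapolated` (TRUE if 0.75 is never crossed inside the tested range),
#'   `data` (the input), `fitted` (per-strength fitted fractions).
#' @export
fit_psychometric <- function(result) {
  stopifnot(is.data.frame(result),
            all(c("flash_strength", "fraction_correct") %in% names(result)))
  if (nrow(result) < 4L)
    stop("need >= 4 flash strengths spanning the transition", call. = FALSE)
  ls <- log10(result$flash_strength)
  fc <- result$fraction_correct
  pred <- function(par) 0.5 + 0.5 * stats::pnorm((ls - par[1]) / exp(par[2]))
  obj <- function(par) sum((fc - pred(par))^2)
  # initial midpoint: strength whose FC is nearest 0.75
  m0 <- ls[which.min(abs(fc - 0.75))]
  opt <- stats::optim(c(m0, log(0.5)), obj)
  m <- opt$par[1]; s <- exp(opt$par[2])
  thr <- 10^m
  extrap <- thr < min(result$flash_strength) | thr > max(result$flash_strength)
  structure(list(m = m, sd = s, threshold_75 = thr, extrapolated = extrap,
                 data = result,
                 fitted = pred(opt$par)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Cumulative-Gaussian psychometric fit (log10 strength)\n")
  cat(sprintf("  midpoint m = %.4f, slope sd = %.4f\n", x$m, x$sd))
  cat(sprintf("  75%%-correct threshold = %.4g Rh*/rod%s\n", x$threshold_75,
              if (x$extrapolated) " (extrapolated)" else ""))
  invisible(x)
}

#' Sweep detection thresholds over a model parameter grid
#'
#' Runs the full 2AFC analysis at each row of a parameter grid and collects
#' the fitted 75%-correct thresholds — e.g. release rate x Erlang factor
#' grids, or comparisons across model families.
#'
#' @param model model id passed to [run_2afc()].
#' @param params base parameter object; each grid row overrides fields by
#'   name.
#' @param grid data frame whose columns name parameter fields to override
#'   (e.g. `E_f`, `R_s`).
#' @param ... passed to [run_2afc()] (`n_rods`, `flash_strengths`,
#'   `n_trials`, ...).
#' @param seed master seed; row i uses `derive_seed(seed, i)`.
#' @return The grid tibble with added columns `threshold_75`, `extrapolated`,
#'   `seed`, `n_trials`.
#' @export
sweep_thresholds <- function(model, params, grid, ..., seed = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  dots <- list(...)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    for (nm in names(grid)) p[[nm]] <- grid[[nm]][i]
    # re-validate through the constructor of the same class
    p <- do.call(class(params)[1], unclass(p))
    args <- c(list(model = model, params = p,
                   seed = derive_seed(seed, i)), dots)
    res <- do.call(run_2afc, args)
    fit <- fit_psychometric(res)
    dplyr::bind_cols(grid[i, , drop = FALSE],
                     tibble::tibble(threshold_75 = fit$threshold_75,
                                    extrapolated = fit$extrapolated,
                                    seed = derive_seed(seed, i),
                                    n_trials = res$n_trials[1]))
  })
  dplyr::bind_rows(rows)
}
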