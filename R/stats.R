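#' Interevent-interval statistics with distribution fits
#'
#' Computes the interval statistics used to characterise release regularity:
#' sample mean, SD, coefficient of variation, the implied Erlang factor
#' `k = 1/CV^2` (an Erlang process accumulating k Poisson intervals per event
#' has interval CV `1/sqrt(k)`), and least-squares exponential and Gaussian
#' fits to the binned interval frequency histogram. `R^2 = 1 - SS_res/SS_tot`
#' throughout and may be negative for badly mismatched models.
#'
#' Distribution fits follow the >50-event inclusion rule used for recordings:
#' with fewer than 50 events the moment statistics are still returned but the
#' histogram fits are `NA`.
#'
#' @param event_times numeric vector of event start times (s), >= 2 events.
#' @param bin_width histogram bin width for the fits (s); default 250 ms.
#' @return A one-row tibble: `n_events`, `n_intervals`, `mean_s`, `sd_s`, `cv`,
#'   `erlang_k`, `exp_tau_s`, `exp_r2`, `gauss_mean_s`, `gauss_sd_s`,
#'   `gauss_r2`.
#' @export
#' @examples
#' set.seed(1)
#' interval_statistics(cumsum(rexp(100, 1)))
interval_statistics <- function(event_times, bin_width = 0.25) {
  if (length(event_times) < 2L)
    stop("undefined statistics: need >= 2 events", call. = FALSE)
  iv <- diff(sort(event_times))
  m <- mean(iv); s <- stats::sd(iv)
  cv <- s / m
  k <- if (cv > 0) 1 / cv^2 else Inf
  out <- tibble::tibble(n_events = length(event_times),
                        n_intervals = length(iv),
                        mean_s = m, sd_s = s, cv = cv, erlang_k = k,
                        exp_tau_s = NA_real_, exp_r2 = NA_real_,
                        gauss_mean_s = NA_real_, gauss_sd_s = NA_real_,
                        gauss_r2 = NA_real_)
  if (length(event_times) < 50L) return(out)
  h <- interval_histogram(iv, bin_width)
  ef <- fit_exponential_hist(h)
  gf <- fit_gaussian_hist(h)
  out$exp_tau_s <- ef$tau; out$exp_r2 <- ef$r2
  out$gauss_mean_s <- gf$mean; out$gauss_sd_s <- gf$sd; out$gauss_r2 <- gf$r2
  out
}

# internal: frequency histogram of intervals
interval_histogram <- function(iv, bin_width) {
  brks <- seq(0, max(iv) + bin_width, by = bin_width)
  cnt <- graphics::hist(iv, breaks = brks, plot = FALSE)$counts
  tibble::tibble(mid = brks[-length(brks)] + bin_width / 2, count = cnt)
}

r_squared <- function(obs, fitted) {
  1 - sum((obs - fitted)^2) / sum((obs - mean(obs))^2)
}

# internal: least-squares A*exp(-t/tau) on histogram counts
fit_exponential_hist <- function(h) {
  pos <- h$count > 0
  init_tau <- tryCatch({
    cf <- stats::coef(stats::lm(log(h$count[pos]) ~ h$mid[pos]))
    if (cf[2] < 0) -1 / cf[2] else mean(h$mid)
  }, error = function(e) mean(h$mid))
  fit <- tryCatch(
    stats::nls(count ~ A * exp(-mid / tau), data = h,
               start = list(A = max(h$count), tau = init_tau),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(tau = NA_real_, r2 = NA_real_))
  list(tau = unname(stats::coef(fit)[["tau"]]),
       r2 = r_squared(h$count, stats::fitted(fit)))
}

# internal: least-squares A*exp(-(t-m)^2/(2 s^2)) on histogram counts
fit_gaussian_hist <- function(h) {
  m0 <- sum(h$mid * h$count) / sum(h$count)
  s0 <- sqrt(sum(h$count * (h$mid - m0)^2) / sum(h$count))
  fit <- tryCatch(
    stats::nls(count ~ A * exp(-(mid - m)^2 / (2 * s^2)), data = h,
               start = list(A = max(h$count), m = m0, s = max(s0, 1e-3)),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(mean = NA_real_, sd = NA_real_, r2 = NA_real_))
  cf <- stats::coef(fit)
  list(mean = unname(cf[["m"]]), sd = abs(unname(cf[["s"]])),
       r2 = r_squared(h$count, stats::fitted(fit)))
}

#' Maximum-likelihood gamma fit to intervals (cross-check utility)
#'
#' The Erlang factor reported by [interval_statistics()] is estimated from the
#' CV identity `k = 1/CV^2`. This utility provides an independent
#' maximum-likelihood gamma fit (continuous-shape Erlang) as a cross-check.
#'
#' @param intervals positive interevent intervals (s).
#' @return A one-row tibble with `shape`, `rate`, `loglik`.
#' @export
fit_gamma_ml <- function(intervals) {
  if (any(intervals <= 0)) stop("intervals must be positive", call. = FALSE)
  nll <- function(p) -sum(stats::dgamma(intervals, shape = exp(p[1]),
                                        rate = exp(p[2]), log = TRUE))
  m <- mean(intervals); v <- stats::var(intervals)
  init <- log(c(m^2 / v, m / v))
  opt <- stats::optim(init, nll)
  tibble::tibble(shape = exp(opt$par[1]), rate = exp(opt$par[2]),
                 loglik = -opt$value)
}

#' Fit the Poisson probability mass function to per-bin event counts
#'
#' Tallies event counts in fixed bins over the recording, forms the fractional
#' frequency distribution of per-bin counts, and fits the Poisson pmf
#' \eqn{P(x) = \lambda^x e^{-\lambda}/x!}. The rate is either constrained to
#' the empirical mean count or fitted freely by least squares. Release that is
#' bimodal per bin (e.g. all-or-none multivesicular quantal counts) yields
#' near-zero or negative `R^2`.
#'
#' @param event_times event start times (s); for quantal-rate fits pass one
#'   time per quantum (see `weights`).
#' @param duration total observation time (s), >= 30 s; defaults to the last
#'   event time rounded up to a whole bin.
#' @param bin bin width (s), default 1.
#' @param lambda_constrained if `TRUE` (default) fix the rate at the empirical
#'   mean count per bin; otherwise fit by least squares.
#' @param weights optional per-event counts (e.g. quanta) so each event
#'   contributes its weight to its bin.
#' @return A one-row tibble: `lambda`, `r2`, `constrained`, `mean_count`.
#' @export
fit_poisson_counts <- function(event_times, duration = NULL, bin = 1,
                               lambda_constrained = TRUE, weights = NULL) {
  if (length(event_times) == 0L) stop("no events", call. = FALSE)
  duration <- duration %||% (ceiling(max(event_times) / bin) * bin)
  if (duration < 30) stop("need >= 30 s of observation", call. = FALSE)
  nb <- floor(duration / bin)
  idx <- pmin(nb, floor(event_times / bin) + 1L)
  w <- weights %||% rep(1, length(event_times))
  counts <- numeric(nb)
  tb <- tapply(w, idx, sum)
  counts[as.integer(names(tb))] <- tb
  counts <- round(counts)
  mean_count <- mean(counts)
  xs <- 0:max(counts)
  freq <- tabulate(counts + 1L, nbins = length(xs)) / nb
  pois_pred <- function(l) stats::dpois(xs, l)
  if (lambda_constrained) {
    lam <- mean_count
  } else {
    obj <- function(l) sum((freq - pois_pred(l))^2)
    lam <- stats::optimize(obj, c(1e-6, max(2 * mean_count, max(counts), 1)))$minimum
  }
  tibble::tibble(lambda = lam, r2 = r_squared(freq, pois_pred(lam)),
                 constrained = lambda_constrained, mean_count = mean_count)
}

#' Peri-stimulus time histogram of event starts
#'
#' Counts event start times in peri-stimulus bins, pooled across repeated
#' stimulus presentations. The total count equals the number of event starts
#' falling inside any window.
#'
#' @param event_starts event start times (s).
#' @param stimulus_onsets stimulus onset times (s), >= 1.
#' @param window `c(pre, post)` window around each onset (s, pre >= 0 counts
#'   backwards).
#' @param bin bin width (s).
#' @return A tibble with `bin_start_s`, `bin_mid_s` (relative to onset) and
#'   `count`, of class `mvr_psth` with `n_stimuli` attribute.
#' @export
psth <- function(event_starts, stimulus_onsets, window = c(2, 8), bin = 0.25) {
  if (length(event_starts) == 0L || length(stimulus_onsets) == 0L)
    stop("empty inputs", call. = FALSE)
  brks <- seq(-window[1], window[2], by = bin)
  rel <- unlist(lapply(stimulus_onsets, function(on) event_starts - on))
  rel <- rel[rel >= -window[1] & rel < max(brks)]
  cnt <- graphics::hist(rel, breaks = brks, plot = FALSE)$counts
  structure(tibble::tibble(bin_start_s = brks[-length(brks)],
                           bin_mid_s = brks[-length(brks)] + bin / 2,
                           count = cnt),
            class = c("mvr_psth", "tbl_df", "tbl", "data.frame"),
            n_stimuli = length(stimulus_onsets))
}

#' Event-triggered average of a stimulus waveform
#'
#' Averages stimulus segments aligned to event start times — the mean voltage
#' trajectory preceding (and following) each detected release event under a
#' white-noise stimulus.
#'
#' @param voltage_stimulus data frame with `time_s` and `voltage_mv`.
#' @param event_starts event start times (s); events without a full pre-window
#'   (or post-window) of stimulus are dropped.
#' @param pre_window,post_window window extent before/after the event (s).
#' @return A tibble of class `mvr_eta` with `lag_s`, `voltage_mv` (mean,
#'   hold-subtracted), `se`; attribute `n_events`.
#' @export
event_triggered_average <- function(voltage_stimulus, event_starts,
                                    pre_window = 2, post_window = 0.5) {
  stopifnot(is.data.frame(voltage_stimulus),
            all(c("time_s", "voltage_mv") %in% names(voltage_stimulus)))
  t0 <- voltage_stimulus$time_s[1L]
  dt_s <- voltage_stimulus$time_s[2L] - t0
  v <- voltage_stimulus$voltage_mv
  n <- length(v)
  npre <- round(pre_window / dt_s); npost <- round(post_window / dt_s)
  centers <- round((event_starts - t0) / dt_s) + 1L
  usable <- centers - npre >= 1L & centers + npost <= n
  centers <- centers[usable]
  if (length(centers) == 0L) stop("no usable events", call. = FALSE)
  segs <- vapply(centers, function(c0) v[(c0 - npre):(c0 + npost)],
                 numeric(npre + npost + 1L))
  mu <- rowMeans(segs)
  se <- apply(segs, 1L, stats::sd) / sqrt(length(centers))
  structure(tibble::tibble(lag_s = (seq(-npre, npost)) * dt_s,
                           voltage_mv = mu - mean(v), se = se),
            class = c("mvr_eta", "tbl_df", "tbl", "data.frame"),
            n_events = length(centers))
}

#' Regression of interevent interval against time after patch rupture
#'
#' Rundown of the release machinery during whole-cell recording slows release;
#' an ordinary least-squares line of interval versus recording time estimates
#' the interval at rupture (intercept) and the slowing rate (slope, s/min).
#'
#' @param intervals interevent intervals (s), >= 10.
#' @param times time of each interval after patch rupture; minutes by default.
#' @param time_unit `"min"` (default) or `"s"`.
#' @return A one-row tibble: `intercept_s`, `slope_s_per_min`, `r2`, `n`.
#' @export
rundown_regression <- function(intervals, times, time_unit = c("min", "s")) {
  time_unit <- match.arg(time_unit)
  if (length(intervals) < 10L) stop("need >= 10 intervals", call. = FALSE)
  tmin <- if (time_unit == "s") times / 60 else times
  if (stats::sd(tmin) == 0) stop("constant time values", call. = FALSE)
  fit <- stats::lm(intervals ~ tmin)
  tibble::tibble(intercept_s = unname(stats::coef(fit)[1]),
                 slope_s_per_min = unname(stats::coef(fit)[2]),
                 r2 = summary(fit)$r.squared,
                 n = length(intervals))
}

#' Rundown-corrected interevent interval and release rate
#'
#' Scales an observed mean interval by the ratio of the rundown-regression
#' intercept (interval at patch rupture) to the overall mean interval,
#' estimating the interval that would be seen before rundown. With the values
#' measured at 35 degrees C (observed 1.13 s, intercept 1.23 s, overall mean
#' 2.26 s) this gives 0.615 s, i.e. 1.6 Hz.
#'
#' @param observed_mean observed mean interval (s).
#' @param intercept rundown-regression intercept (s).
#' @param overall_mean overall mean interval in the rundown sample (s).
#' @return A one-row tibble: `corrected_interval_s`, `rate_hz` (1/interval,
#'   rounded to one decimal).
#' @export
#' @examples
#' rundown_corrected_interval(1.13, 1.23, 2.26)
rundown_corrected_interval <- function(observed_mean, intercept, overall_mean) {
  check_positive(observed_mean, "observed_mean")
  check_positive(intercept, "intercept")
  check_positive(overall_mean, "overall_mean")
  corrected <- observed_mean * intercept / overall_mean
  tibble::tibble(corrected_interval_s = corrected,
                 rate_hz = release_rate_hz(corrected))
}

#' Release rate implied by an interevent interval
#'
#' @param interval_s interevent interval (s), > 0.
#' @return Rate in Hz, rounded to one decimal.
#' @export
#' @examples
#' release_rate_hz(0.465) # 2.2
release_rate_hz <- function(interval_s) {
  if (any(interval_s <= 0)) stop("interval must be positive", call. = FALSE)
  round(1 / interval_s, 1)
}
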