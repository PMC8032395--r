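#' Event detection settings
#'
#' Parameters for scaled-template (Clements-Bekkers) event detection: the
#' template waveform, the detection-criterion threshold (fitted scale divided
#' by its standard error), and a refractory window within which overlapping
#' detections are merged.
#'
#' @param template numeric waveform (same sample interval as the trace to be
#'   searched); defaults to the unitary template at 1 ms.
#' @param correlation_threshold detection-criterion threshold, in `(0, 10]`.
#' @param refractory merge window (ms), >= 0.
#' @return A list of class `detection_settings`.
#' @export
detection_settings <- function(template = make_unitary_template(dt = 1),
                               correlation_threshold = 4,
                               refractory = 10) {
  if (correlation_threshold <= 0 || correlation_threshold > 10)
    stop("`correlation_threshold` must lie in (0, 10]", call. = FALSE)
  check_positive(refractory, "refractory", strict = FALSE)
  structure(list(template = template,
                 correlation_threshold = correlation_threshold,
                 refractory = refractory),
            class = "detection_settings")
}

#' Detect release events in a current trace by scaled-template matching
#'
#' Slides the template along the trace; at each offset the template is fitted
#' by least squares with a free scale and offset, and the Clements-Bekkers
#' detection criterion (scale / standard error of the fit) is computed.
#' Local criterion maxima above threshold, separated by at least the
#' refractory window, are reported as events with their peak amplitude
#' (baseline-subtracted) and charge.
#'
#' @param trace a data frame with columns `time_s` and `current_pA` (e.g. the
#'   `trace` element of [simulate_trace()] output).
#' @param settings a [detection_settings()].
#' @return A tibble with columns `start_s`, `peak_pA`, `charge_pC`, and
#'   `criterion`; zero rows when nothing crosses threshold.
#' @export
detect_events <- function(trace, settings = detection_settings()) {
  stopifnot(is.data.frame(trace), all(c("time_s", "current_pA") %in% names(trace)))
  x <- trace$current_pA
  n <- length(x)
  if (n == 0L) stop("empty trace", call. = FALSE)
  w <- settings$template
  L <- length(w)
  if (L >= n) stop("template must be shorter than the trace", call. = FALSE)
  dt_s <- trace$time_s[2L] - trace$time_s[1L]

  # rolling sums via convolution with a length-L boxcar / reversed template
  sw <- sum(w); sw2 <- sum(w^2)
  csx <- c(0, cumsum(x)); csx2 <- c(0, cumsum(x^2))
  nwin <- n - L + 1L
  Sx <- csx[(L + 1L):(n + 1L)] - csx[1:nwin]
  Sx2 <- csx2[(L + 1L):(n + 1L)] - csx2[1:nwin]
  # Swx[i] = sum_j w[j] * x[i + j - 1]
  Swx <- as.numeric(stats::filter(x, rev(w), sides = 1))[L:n]

  denom <- sw2 - sw^2 / L
  scale <- (Swx - sw * Sx / L) / denom
  offset <- (Sx - scale * sw) / L
  sse <- Sx2 + scale^2 * sw2 + L * offset^2 -
    2 * (scale * Swx + offset * Sx - scale * offset * sw)
  sse <- pmax(sse, 0)
  # detection statistic = fitted scale / its standard error (t-like: ~N(0,1)
  # on pure noise, so the threshold is in noise SDs of the scale estimate)
  se_scale <- sqrt(sse / (L - 1) / denom)
  crit <- scale / pmax(se_scale, .Machine$double.eps)

  thr <- settings$correlation_threshold
  above <- which(crit >= thr)
  if (length(above) == 0L) {
    return(tibble::tibble(start_s = numeric(0), peak_pA = numeric(0),
                          charge_pC = numeric(0), criterion = numeric(0)))
  }
  # group contiguous/refractory-close runs, then split each run at deep
  # criterion dips so overlapping events separated by a clear trough are kept
  # as distinct detections while noise jitter around one event is merged
  ref_pts <- max(1L, round(settings$refractory / (dt_s * 1000)))
  gaps <- c(Inf, diff(above))
  grp <- cumsum(gaps > ref_pts)
  starts <- unlist(lapply(split(above, grp), function(ix) {
    # each run opens one event at the threshold crossing; additional events
    # inside the run are opened at the criterion trough preceding any later
    # local maximum separated from the previous one by a deep dip
    if (length(ix) == 1L) return(ix)
    cr <- crit[ix]
    locmax <- which(cr >= c(-Inf, cr[-length(cr)]) &
                      cr >= c(cr[-1], -Inf) & cr >= thr)
    if (length(locmax) <= 1L) return(ix[1L])
    out <- 1L
    last <- locmax[1L]
    for (m in locmax[-1L]) {
      tr_i <- last + which.min(cr[last:m]) - 1L
      if (m - last > ref_pts && cr[tr_i] < 0.45 * min(cr[last], cr[m])) {
        out <- c(out, tr_i)
        last <- m
      } else if (cr[m] > cr[last]) {
        last <- m
      }
    }
    ix[out]
  }), use.names = FALSE)
  starts <- unname(sort(starts))

  # per-event peak and charge: baseline from the pre-event segment, window
  # extended well past the template (compound events outlast one unitary
  # decay) but capped at the next detection; the peak is read from a lightly
  # smoothed segment so it is not biased by the extreme of the noise
  win_pts <- round(2.5 * L)
  base_pts <- max(5L, round(0.25 * L))
  sm_pts <- max(1L, round(0.007 / dt_s))
  sm_kern <- rep(1 / sm_pts, sm_pts)
  margin <- round(0.3 * L) # a slow event crosses threshold tens of ms late
  out <- lapply(seq_along(starts), function(k) {
    i0 <- starts[k]
    nxt <- if (k < length(starts)) starts[k + 1L] else n + margin
    i1 <- min(n, i0 + win_pts - 1L, max(i0 + round(L / 2), nxt - margin))
    # the threshold crossing lags a slow compound onset by tens of ms, so the
    # baseline window ends one margin before the detection and the charge
    # integral starts up to one margin before it (half the gap to the
    # previous event at most). Peak baseline: low percentile, robust to a
    # previous event's decaying tail; charge baseline: median (unbiased in
    # noise, where a percentile would inflate every sample of the window).
    b1 <- max(1L, i0 - margin)
    b0 <- max(1L, b1 - 4L * base_pts)
    pre <- x[b0:max(b0, b1 - 1L)]
    base_pk <- stats::quantile(pre, 0.2, names = FALSE)
    base_q <- stats::median(pre)
    gap_prev <- if (k > 1L) i0 - starts[k - 1L] else i0
    j0 <- max(1L, i0 - min(margin, gap_prev %/% 2L))
    seg <- x[i0:i1] - base_pk
    sm <- if (length(seg) > sm_pts) {
      as.numeric(stats::filter(seg, sm_kern, sides = 2))
    } else seg
    list(start_s = trace$time_s[i0],
         peak_pA = max(sm, na.rm = TRUE),
         charge_pC = sum(x[j0:i1] - base_q) * dt_s, # pA * s = pC
         criterion = crit[i0])
  })
  dplyr::bind_rows(lapply(out, tibble::as_tibble))
}

#' Classify detected events as unitary or multivesicular
#'
#' Fits a two-component Gaussian mixture to event amplitudes (EM algorithm)
#' and labels each event by posterior probability. If the two-component fit
#' does not beat a single Gaussian by BIC the distribution is declared
#' unimodal and every event is labelled unitary, with `unimodal = TRUE`
#' recorded as an attribute.
#'
#' @param events a data frame of detected events with a `peak_pA` column
#'   (from [detect_events()]).
#' @param on column to classify on, `"peak_pA"` (default) or `"charge_pC"`.
#' @return The input tibble with added columns `class`
#'   (`"unitary"`/`"multivesicular"`) and `posterior_mve`; attributes
#'   `boundary` (amplitude at equal posterior), `unimodal`, and `mixture`
#'   (fitted component weights, means and SDs).
#' @export
classify_events <- function(events, on = "peak_pA") {
  stopifnot(is.data.frame(events), on %in% names(events))
  a <- events[[on]]
  if (length(a) < 10L) stop("need >= 10 events to classify", call. = FALSE)
  fit2 <- fit_gaussian_mixture(a)
  # single-component BIC
  ll1 <- sum(stats::dnorm(a, mean(a), stats::sd(a) + 1e-12, log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(length(a))
  unimodal <- is.null(fit2) || fit2$bic >= bic1
  out <- dplyr::as_tibble(events)
  if (unimodal) {
    out$class <- "unitary"
    out$posterior_mve <- 0
    attr(out, "unimodal") <- TRUE
    attr(out, "boundary") <- NA_real_
    warning("amplitude distribution unimodal; all events labelled unitary",
            call. = FALSE)
    return(out)
  }
  hi <- which.max(fit2$mu) # the larger-mean component is multivesicular
  post <- fit2$posterior[, hi]
  out$class <- ifelse(post > 0.5, "multivesicular", "unitary")
  out$posterior_mve <- post
  lo <- which.min(fit2$mu)
  bnd <- tryCatch(stats::uniroot(function(z) {
    fit2$pi[hi] * stats::dnorm(z, fit2$mu[hi], fit2$sigma[hi]) -
      fit2$pi[lo] * stats::dnorm(z, fit2$mu[lo], fit2$sigma[lo])
  }, lower = fit2$mu[lo], upper = fit2$mu[hi])$root, error = function(e) NA_real_)
  attr(out, "unimodal") <- FALSE
  attr(out, "boundary") <- bnd
  attr(out, "mixture") <- tibble::tibble(
    component = ifelse(fit2$mu == min(fit2$mu), "unitary", "multivesicular"),
    pi = fit2$pi, mu = fit2$mu, sigma = fit2$sigma)
  out
}

# internal: two-component Gaussian mixture by EM (no mixture package in the
# supported environment). Returns NULL on degenerate input.
fit_gaussian_mixture <- function(x, max_iter = 200, tol = 1e-8) {
  n <- length(x)
  if (stats::sd(x) == 0) return(NULL)
  q <- stats::quantile(x, c(0.25, 0.75))
  mu <- as.numeric(q)
  if (diff(mu) == 0) mu <- mu + c(-1, 1) * stats::sd(x) / 2
  sigma <- rep(stats::sd(x) / 2, 2)
  pi_k <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi_k[1] * stats::dnorm(x, mu[1], sigma[1])
    d2 <- pi_k[2] * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- cbind(d1, d2) / tot
    nk <- colSums(g)
    if (any(nk < 1e-8)) return(NULL)
    pi_k <- nk / n
    mu <- colSums(g * x) / nk
    sigma <- sqrt(pmax(colSums(g * (x - rep(mu, each = n))^2) / nk, 1e-12))
    sigma <- pmax(sigma, 1e-4 * stats::sd(x))
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(pi = pi_k, mu = mu, sigma = sigma, posterior = g,
       loglik = ll, bic = -2 * ll + 5 * log(n))
}

#' Quantal content of an event from its charge transfer
#'
#' Estimates the number of vesicles in an event by dividing its total charge
#' transfer by the mean charge transfer of unitary events, rounding to the
#' nearest integer (minimum 1).
#'
#' @param event_charge event charge(s), pC; must be positive.
#' @param mean_unitary_charge mean unitary charge, pC; must be positive.
#' @return Integer vector of quantal counts.
#' @export
#' @examples
#' quantal_count(17 * 0.05, 0.05) # 17
quantal_count <- function(event_charge, mean_unitary_charge) {
  check_positive(mean_unitary_charge, "mean_unitary_charge")
  if (any(!is.finite(event_charge)) || any(event_charge <= 0))
    stop("event charges must be positive", call. = FALSE)
  pmax(1L, as.integer(round(event_charge / mean_unitary_charge)))
}
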