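#' Alpha waveform for a multivesicular release event
#'
#' The compound transporter-current deflection produced by a multivesicular
#' event is modelled as an alpha function
#' \deqn{M(t) = a \, (t/\tau_r) \, e^{1 - t/\tau_r}}
#' which rises from zero, peaks at exactly `a` when `t == tau_r`, and decays
#' back towards zero. The closed-form time integral of one event is
#' `a * tau_r * e`.
#'
#' @param t numeric vector of times (s), may include negative values (zero
#'   before onset).
#' @param a peak amplitude (release units).
#' @param tau_r time-to-peak (s), must be positive.
#' @return Numeric vector `M(t)`, zero for `t <= 0`.
#' @export
#' @examples
#' alpha_waveform(0.025, a = 1, tau_r = 0.025) # == 1 at the peak
alpha_waveform <- function(t, a = 1, tau_r = 0.025) {
  check_positive(tau_r, "tau_r")
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- a * (t[pos] / tau_r) * exp(1 - t[pos] / tau_r)
  out
}

#' Superpose alpha waveforms at event times onto a time grid
#'
#' Realises a continuous release trace from a set of delta-function event
#' times by convolution with [alpha_waveform()]. Linear in events: coincident
#' events sum.
#'
#' @param event_times numeric vector of event times (s).
#' @param grid numeric vector of sample times (s), uniformly spaced.
#' @param a,tau_r alpha-waveform parameters (see [alpha_waveform()]).
#' @return Numeric vector of the same length as `grid`.
#' @export
alpha_convolve <- function(event_times, grid, a = 1, tau_r = 0.025) {
  check_positive(tau_r, "tau_r")
  n <- length(grid)
  if (n < 2L) stop("`grid` must have at least 2 samples", call. = FALSE)
  dt <- grid[2L] - grid[1L]
  out <- numeric(n)
  if (length(event_times) == 0L) return(out)
  # bin events onto the grid, then convolve once with the sampled kernel
  idx <- round((event_times - grid[1L]) / dt) + 1L
  keep <- idx >= 1L & idx <= n
  idx <- idx[keep]
  if (length(idx) == 0L) return(out)
  impulses <- tabulate(idx, nbins = n)
  klen <- min(n, ceiling(10 * tau_r / dt))
  kern <- alpha_waveform(seq_len(klen) * dt - dt, a = a, tau_r = tau_r)
  full <- stats::convolve(impulses, rev(kern), type = "open")
  full[seq_len(n)]
}

#' Unitary transporter-current event template
#'
#' Builds a unit-amplitude waveform for a single-vesicle transporter current:
#' an exponential-saturation rise multiplied by an exponential decay,
#' \eqn{(1 - e^{-t/\tau_{rise}})\, e^{-t/\tau_{decay}}}, renormalised to peak
#' 1. The rise time constant is solved numerically so the sampled 10-90% rise
#' time matches `rise_10_90` (rods show 9-10 ms rises with ~40 ms decays).
#'
#' @param rise_10_90 target 10-90% rise time (ms).
#' @param decay_tau decay time constant (ms).
#' @param dt sample interval (ms), must be <= 1 ms and < `decay_tau`.
#' @param duration template length (ms); default covers 5 decay constants.
#' @return Numeric vector, unit peak amplitude, starting at 0.
#' @export
#' @examples
#' w <- make_unitary_template(9.5, 40, dt = 0.1)
#' max(w) # 1
make_unitary_template <- function(rise_10_90 = 9.5, decay_tau = 40,
                                  dt = 0.1, duration = NULL) {
  check_positive(rise_10_90, "rise_10_90")
  check_positive(decay_tau, "decay_tau")
  check_positive(dt, "dt")
  if (dt > decay_tau) stop("invalid resolution: `dt` exceeds `decay_tau`",
                           call. = FALSE)
  if (dt > 1) stop("`dt` must be <= 1 ms to resolve the rising phase",
                   call. = FALSE)
  duration <- duration %||% (5 * decay_tau)
  t <- seq(0, duration, by = dt)
  build <- function(tau_rise) {
    w <- (1 - exp(-t / tau_rise)) * exp(-t / decay_tau)
    w / max(w)
  }
  # measured rise grows monotonically with tau_rise; bracket then root-find
  f <- function(tau_rise) measure_rise_10_90(build(tau_rise), dt) - rise_10_90
  sol <- stats::uniroot(f, lower = dt / 10, upper = 10 * rise_10_90,
                        tol = dt / 100)
  build(sol$root)
}
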