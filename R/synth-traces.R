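#' Unitary event shape parameters
#'
#' Kinetic and amplitude description of the transporter current evoked by a
#' single released vesicle. Defaults are the values measured in rods held at
#' -40 mV (unitary amplitude 1.35 +/- 0.685 pA, 10-90% rise ~9.5 ms, decay
#' time constant ~40 ms); at -70 mV the unitary amplitude is 1.51 +/- 0.688 pA.
#'
#' @param amplitude_mean mean unitary amplitude (pA), > 0.
#' @param amplitude_sd SD of unitary amplitudes (pA), >= 0.
#' @param amplitude_floor smallest unitary amplitude (pA): draws follow the
#'   fitted Gaussian truncated below this visibility floor, matching the
#'   support of the observed amplitude histograms.
#' @param rise_10_90 10-90% rise time (ms), > 0.
#' @param decay_tau decay time constant (ms), > 0.
#' @return A list of class `unitary_shape`.
#' @export
unitary_event_shape <- function(amplitude_mean = 1.35, amplitude_sd = 0.685,
                                amplitude_floor = 0.4,
                                rise_10_90 = 9.5, decay_tau = 40) {
  check_positive(amplitude_mean, "amplitude_mean")
  check_positive(amplitude_sd, "amplitude_sd", strict = FALSE)
  check_positive(amplitude_floor, "amplitude_floor", strict = FALSE)
  check_positive(rise_10_90, "rise_10_90")
  check_positive(decay_tau, "decay_tau")
  structure(list(amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 amplitude_floor = amplitude_floor,
                 rise_10_90 = rise_10_90, decay_tau = decay_tau),
            class = "unitary_shape")
}

#' Synthetic recording parameters
#'
#' Full parameterisation of a synthetic transporter-current recording: a
#' homogeneous Poisson process of unitary events plus an independent renewal
#' process of multivesicular events with Gaussian-distributed interevent
#' intervals (truncated at a 100 ms floor). Defaults reproduce the statistics
#' reported for rods held at -40 mV: unitary rate ~1/s, multivesicular
#' intervals 2.34 s mean with CV 0.43, ~17 +/- 7 vesicles per event.
#'
#' @param duration recording length (s).
#' @param dt sample interval (ms).
#' @param unitary_rate unitary event rate (events/s), >= 0.
#' @param mve_interval_mean mean multivesicular interevent interval (s); set to
#'   `Inf` or `0` rate via `mve_rate_off = TRUE` is not needed — use
#'   `mve_interval_mean = Inf` to disable multivesicular events.
#' @param mve_interval_cv coefficient of variation of the intervals, in `[0, 1]`.
#' @param mve_quanta_mean,mve_quanta_sd Gaussian parameters for the vesicle
#'   count per multivesicular event (rounded, floored at `mve_quanta_floor`).
#' @param mve_quanta_floor minimum vesicles per multivesicular event; the
#'   default 6 keeps the class consistent with the reported 10-20-vesicle
#'   events and the cleanly bimodal amplitude histograms.
#' @param intra_event_spacing_mean mean spacing between quanta within one
#'   multivesicular event (ms).
#' @param intra_event_spacing_shape gamma shape of the intra-event spacings;
#'   the default (8, CV 0.35) models quasi-regular sequential release down
#'   the ribbon, so the ~17 quanta superpose into one smooth ~100 ms
#'   compound deflection whose amplitude distribution peaks near the
#'   reported 9.6 pA given the unitary kinetics.
#' @param recording_noise_sd additive white Gaussian recording noise (pA).
#' @param rundown_interval_slope growth of the mean interval with time after
#'   patch rupture (s/min); 0 disables rundown.
#' @param rundown_amp_ramp amplitude ramp (fraction/min) modelling SCN-
#'   diffusion from the pipette over the first minutes; amplitudes scale by
#'   `min(1, 1 - 3*ramp + ramp*t_min)`, saturating at 3 min. 0 disables.
#' @param holding_potential holding potential (mV), metadata only.
#' @param unitary_shape a [unitary_event_shape()].
#' @param seed integer seed.
#' @return A list of class `synth_trace_params`.
#' @export
synth_trace_params <- function(duration = 180, dt = 1,
                               unitary_rate = 1,
                               mve_interval_mean = 2.34,
                               mve_interval_cv = 0.43,
                               mve_quanta_mean = 17, mve_quanta_sd = 7,
                               mve_quanta_floor = 6,
                               intra_event_spacing_mean = 10,
                               intra_event_spacing_shape = 8,
                               recording_noise_sd = 0.3,
                               rundown_interval_slope = 0,
                               rundown_amp_ramp = 0,
                               holding_potential = -40,
                               unitary_shape = unitary_event_shape(),
                               seed = 1L) {
  check_positive(duration, "duration")
  check_positive(dt, "dt")
  check_positive(unitary_rate, "unitary_rate", strict = FALSE)
  if (!is.numeric(mve_interval_mean) || mve_interval_mean <= 0)
    stop("`mve_interval_mean` must be positive (Inf disables)", call. = FALSE)
  if (mve_interval_cv < 0 || mve_interval_cv > 1)
    stop("`mve_interval_cv` must lie in [0, 1]", call. = FALSE)
  check_positive(mve_quanta_mean, "mve_quanta_mean")
  check_positive(recording_noise_sd, "recording_noise_sd", strict = FALSE)
  structure(list(duration = duration, dt = dt, unitary_rate = unitary_rate,
                 mve_interval_mean = mve_interval_mean,
                 mve_interval_cv = mve_interval_cv,
                 mve_quanta_mean = mve_quanta_mean,
                 mve_quanta_sd = mve_quanta_sd,
                 mve_quanta_floor = mve_quanta_floor,
                 intra_event_spacing_mean = intra_event_spacing_mean,
                 intra_event_spacing_shape = intra_event_spacing_shape,
                 recording_noise_sd = recording_noise_sd,
                 rundown_interval_slope = rundown_interval_slope,
                 rundown_amp_ramp = rundown_amp_ramp,
                 holding_potential = holding_potential,
                 unitary_shape = unitary_shape,
                 seed = as.integer(seed)),
            class = "synth_trace_params")
}

#' Voltage-command protocols
#'
#' Constructors for the four stimulus protocols applied to the synthetic rod:
#' a constant hold, a small hyperpolarising step, repeats of the single-photon
#' voltage waveform, and band-limited white noise.
#'
#' `protocol_step()` carries the interval statistics measured at the stepped
#' potential (defaults: text values 2.405 s at -40 mV vs 3.744 s at -43.5 mV;
#' the Gaussian-fit values 1.583/2.896 s from the pooled histograms are an
#' alternative parameter set).
#'
#' @param hold_mv holding potential (mV).
#' @param onset_s step onset (s).
#' @param to_mv stepped potential (mV).
#' @param interval_mean_stepped,interval_sd_stepped multivesicular interval
#'   mean/SD (s) while stepped.
#' @param onsets numeric vector of stimulus onset times (s) for repeated
#'   single-photon waveforms.
#' @param peak_mv,t_peak_ms,decay_tau_s single-photon waveform parameters
#'   (hyperpolarisation peak magnitude mV, time-to-peak ms, decay s).
#' @param rebound_frac,rebound_tau_s,v_half_mv voltage-to-intensity mapping:
#'   release intensity is `base * max(0, 1 - |dV|/v_half_mv)` during
#'   hyperpolarisation and overshoots baseline by `rebound_frac` decaying with
#'   `rebound_tau_s` after recovery.
#' @param sd_mv,cutoff_hz white-noise SD (mV) and high-frequency cutoff (Hz).
#' @param intensity_lp_hz corner frequency (Hz) of the two-pole low-pass
#'   applied to voltage before the intensity mapping (the terminal responds to
#'   slow voltage changes only).
#' @return A list of class `voltage_protocol`.
#' @name voltage_protocol
NULL

#' @rdname voltage_protocol
#' @export
protocol_constant <- function(hold_mv = -40) {
  structure(list(kind = "constant", hold_mv = hold_mv),
            class = "voltage_protocol")
}

#' @rdname voltage_protocol
#' @export
protocol_step <- function(onset_s = 30, hold_mv = -40, to_mv = -43.5,
                          interval_mean_stepped = 3.744,
                          interval_sd_stepped = 2.243) {
  check_positive(onset_s, "onset_s")
  structure(list(kind = "step", onset_s = onset_s, hold_mv = hold_mv,
                 to_mv = to_mv,
                 interval_mean_stepped = interval_mean_stepped,
                 interval_sd_stepped = interval_sd_stepped),
            class = "voltage_protocol")
}

#' @rdname voltage_protocol
#' @export
protocol_spr <- function(onsets = 5, hold_mv = -40, peak_mv = 3.4,
                         t_peak_ms = 245, decay_tau_s = 2.5,
                         stim_duration_s = 3, rebound_frac = 0.5,
                         rebound_tau_s = 0.5, v_half_mv = 1.0) {
  structure(list(kind = "single_photon_waveform", onsets = onsets,
                 hold_mv = hold_mv, peak_mv = peak_mv, t_peak_ms = t_peak_ms,
                 decay_tau_s = decay_tau_s, stim_duration_s = stim_duration_s,
                 rebound_frac = rebound_frac,
                 rebound_tau_s = rebound_tau_s, v_half_mv = v_half_mv),
            class = "voltage_protocol")
}

#' @rdname voltage_protocol
#' @export
protocol_white_noise <- function(sd_mv = 3.5, cutoff_hz = 5, hold_mv = -40,
                                 v_half_mv = 1.0, intensity_lp_hz = 1.5) {
  check_positive(cutoff_hz, "cutoff_hz")
  check_positive(sd_mv, "sd_mv", strict = FALSE)
  structure(list(kind = "white_noise", sd_mv = sd_mv, cutoff_hz = cutoff_hz,
                 hold_mv = hold_mv, v_half_mv = v_half_mv,
                 intensity_lp_hz = intensity_lp_hz),
            class = "voltage_protocol")
}

#' Single-photon voltage waveform
#'
#' Difference-of-exponentials hyperpolarisation mimicking the mouse rod
#' single-photon voltage response: peak magnitude 3.4 mV reached 245 ms after
#' onset, then decaying with a 2.5 s time constant. The rising time constant is
#' solved numerically from the peak-time identity
#' `t_peak = log(tau_d/tau_r) * tau_d * tau_r / (tau_d - tau_r)`.
#'
#' @param duration waveform length (s).
#' @param dt sample interval (ms).
#' @param t_peak_ms time of peak hyperpolarisation (ms).
#' @param peak_mv peak magnitude (mV); output is negative-going.
#' @param decay_tau_s decay time constant (s).
#' @return A tibble with columns `time_s` and `voltage_mv` (0 at t = 0).
#' @export
#' @examples
#' w <- spr_voltage_waveform(duration = 2, dt = 1)
#' min(w$voltage_mv) # -3.4
spr_voltage_waveform <- function(duration = 10, dt = 1, t_peak_ms = 245,
                                 peak_mv = 3.4, decay_tau_s = 2.5) {
  check_positive(t_peak_ms, "t_peak_ms")
  check_positive(decay_tau_s, "decay_tau_s")
  check_positive(peak_mv, "peak_mv")
  tp <- t_peak_ms / 1000
  td <- decay_tau_s
  # solve for the rising time constant from the peak-time identity
  f <- function(tr) log(td / tr) * td * tr / (td - tr) - tp
  tr <- stats::uniroot(f, lower = 1e-5, upper = td * 0.999, tol = 1e-9)$root
  t <- seq(0, duration, by = dt / 1000)
  raw <- exp(-t / td) - exp(-t / tr)
  v <- -peak_mv * raw / max(raw)
  tibble::tibble(time_s = t, voltage_mv = v)
}

#' Band-limited white-noise voltage stimulus
#'
#' Zero-mean Gaussian noise brick-wall low-pass filtered in the frequency
#' domain at `cutoff_hz`, then rescaled so the realised standard deviation
#' equals `sd_mv` exactly.
#'
#' @param sd_mv target SD (mV); 0 yields an all-zero trace.
#' @param cutoff_hz high-frequency cutoff (Hz); must be below Nyquist.
#' @param duration length (s).
#' @param dt sample interval (ms).
#' @param seed integer seed.
#' @return A tibble with columns `time_s` and `voltage_mv`.
#' @export
white_noise_voltage <- function(sd_mv = 3.5, cutoff_hz = 5, duration = 60,
                                dt = 1, seed = 1L) {
  check_positive(sd_mv, "sd_mv", strict = FALSE)
  check_positive(cutoff_hz, "cutoff_hz")
  fs <- 1000 / dt
  if (cutoff_hz >= fs / 2)
    stop("`cutoff_hz` must be below the Nyquist frequency", call. = FALSE)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  if (sd_mv == 0) return(tibble::tibble(time_s = t, voltage_mv = numeric(n)))
  set.seed(seed)
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  freq <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  xf[abs(freq) > cutoff_hz] <- 0
  y <- Re(stats::fft(xf, inverse = TRUE)) / n
  y <- y - mean(y)
  y <- y * sd_mv / stats::sd(y)
  tibble::tibble(time_s = t, voltage_mv = y)
}

#' Time-varying multivesicular release modulation under a voltage protocol
#'
#' Maps a voltage protocol onto the parameters of the multivesicular renewal
#' process over a trace. For step protocols the interval mean/SD switch to the
#' stepped values at step onset. For single-photon-waveform and white-noise
#' protocols the instantaneous (low-pass filtered) voltage deviation from hold
#' sets a relative hazard `max(0, 1 + dV/v_half)` (hyperpolarisation `dV < 0`
#' suppresses; ~1 mV abolishes release), and after each single-photon waveform
#' recovers the hazard overshoots baseline by `rebound_frac`, decaying with
#' `rebound_tau_s`.
#'
#' @param base_interval_stats list with `mean` and `sd` of the baseline
#'   multivesicular interevent interval (s).
#' @param protocol a [voltage_protocol] object.
#' @param duration trace length (s).
#' @param dt sample interval (ms).
#' @param seed integer seed for the white-noise stimulus realisation (ignored
#'   by the deterministic protocols).
#' @return A tibble with columns `time_s`, `voltage_mv`, `intensity_rel`
#'   (relative hazard, 1 = baseline), `interval_mean`, `interval_sd`.
#' @export
modulate_rates <- function(base_interval_stats, protocol, duration, dt = 1,
                           seed = 1L) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  fs <- 1000 / dt
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  m0 <- base_interval_stats$mean
  s0 <- base_interval_stats$sd
  out <- tibble::tibble(time_s = t,
                        voltage_mv = rep(protocol$hold_mv %||% -40, n),
                        intensity_rel = rep(1, n),
                        interval_mean = rep(m0, n),
                        interval_sd = rep(s0, n))
  if (protocol$kind == "constant") return(out)
  if (protocol$kind == "step") {
    stepped <- t >= protocol$onset_s
    out$voltage_mv[stepped] <- protocol$to_mv
    out$interval_mean[stepped] <- protocol$interval_mean_stepped
    out$interval_sd[stepped] <- protocol$interval_sd_stepped
    return(out)
  }
  if (protocol$kind == "single_photon_waveform") {
    v <- rep(0, n)
    # the command waveform is applied for stim_duration_s, then steps back to
    # hold; release rebounds above baseline right after termination
    wav <- spr_voltage_waveform(duration = protocol$stim_duration_s,
                                dt = dt, t_peak_ms = protocol$t_peak_ms,
                                peak_mv = protocol$peak_mv,
                                decay_tau_s = protocol$decay_tau_s)$voltage_mv
    reb <- rep(0, n)
    for (on in protocol$onsets) {
      i0 <- round(on * fs) + 1L
      if (i0 > n) next
      span <- i0:min(n, i0 + length(wav) - 1L)
      v[span] <- v[span] + wav[seq_along(span)]
      rec <- i0 + length(wav)
      if (rec <= n) {
        span2 <- rec:n
        trel <- (span2 - rec) / fs
        reb[span2] <- reb[span2] +
          protocol$rebound_frac * exp(-trel / protocol$rebound_tau_s)
      }
    }
    out$voltage_mv <- protocol$hold_mv + v
    out$intensity_rel <- pmax(0, 1 - abs(pmin(v, 0)) / protocol$v_half_mv) *
      (1 + reb)
    return(out)
  }
  if (protocol$kind == "white_noise") {
    wn <- white_noise_voltage(sd_mv = protocol$sd_mv,
                              cutoff_hz = protocol$cutoff_hz,
                              duration = duration, dt = dt, seed = seed)
    v <- wn$voltage_mv
    # terminal intensity follows slow voltage only: two-pole low-pass, so
    # fast fluctuations (>= ~20 Hz) are strongly attenuated while the rod
    # band (<= ~5 Hz) passes
    a <- exp(-2 * pi * protocol$intensity_lp_hz / fs)
    vf <- as.numeric(stats::filter(v * (1 - a), filter = a,
                                   method = "recursive"))
    vf <- as.numeric(stats::filter(vf * (1 - a), filter = a,
                                   method = "recursive"))
    out$voltage_mv <- protocol$hold_mv + v
    out$intensity_rel <- pmax(0, 1 + vf / protocol$v_half_mv)
    return(out)
  }
  stop("unknown protocol kind: ", protocol$kind, call. = FALSE)
}

# internal: draw multivesicular event start times over [0, duration]
# following the modulation table; renewal with truncated-Gaussian intervals.
# For constant/step: regime parameters in effect at the draw time; for
# voltage-mapped protocols: hazard rescaling of the baseline renewal.
draw_mve_times <- function(params, mod, duration) {
  m0 <- params$mve_interval_mean
  if (!is.finite(m0)) return(numeric(0))
  floor_s <- 0.1
  slope <- params$rundown_interval_slope
  dt_s <- mod$time_s[2L] - mod$time_s[1L]
  hazard_mapped <- any(mod$intensity_rel != 1)
  times <- numeric(0)
  if (!hazard_mapped) {
    t <- 0
    repeat {
      i <- min(length(mod$interval_mean), floor(t / dt_s) + 1L)
      m <- mod$interval_mean[i] + slope * t / 60
      s <- mod$interval_sd[i]
      iv <- max(floor_s, stats::rnorm(1L, m, s))
      t <- t + iv
      if (t >= duration) break
      times <- c(times, t)
    }
  } else {
    # operational-time rescaling of the baseline renewal through the hazard
    C <- cumsum(mod$intensity_rel) * dt_s
    s0 <- params$mve_interval_cv * m0
    op <- 0
    repeat {
      iv <- max(floor_s, stats::rnorm(1L, m0, s0))
      op <- op + iv
      i <- findInterval(op, C) + 1L
      if (i > length(C)) break
      times <- c(times, mod$time_s[i])
    }
  }
  times
}

#' Simulate a synthetic transporter-current recording
#'
#' Generates a current trace with the statistical structure measured in rod
#' terminals: unitary events placed by a homogeneous Poisson process,
#' multivesicular events placed by a truncated-Gaussian renewal process (each
#' realised as `quanta` unitary waveforms at exponential intra-event spacings),
#' optional voltage-protocol modulation of the multivesicular process, optional
#' rundown, and additive Gaussian recording noise. Ground truth is returned
#' exactly.
#'
#' @param params a [synth_trace_params()].
#' @param protocol a [voltage_protocol] object; default constant hold.
#' @return A list of class `mvr_simulation` with elements
#'   \describe{
#'     \item{trace}{tibble `time_s`, `current_pA` (positive-going events)}
#'     \item{events}{ground-truth tibble `start_s`, `class`
#'       (`"unitary"`/`"multivesicular"`), `quanta`, `peak_pA`, `charge_pC`}
#'     \item{modulation}{the [modulate_rates()] table used}
#'   }
#'   with `params`, `protocol` and `seed` attached as attributes.
#' @export
#' @examples
#' sim <- simulate_trace(synth_trace_params(duration = 30, seed = 2))
#' nrow(sim$events)
simulate_trace <- function(params, protocol = protocol_constant()) {
  stopifnot(inherits(params, "synth_trace_params"),
            inherits(protocol, "voltage_protocol"))
  if (params$unitary_rate < 0) stop("negative rates", call. = FALSE)
  set.seed(params$seed)
  dur <- params$duration
  dt_ms <- params$dt
  fs <- 1000 / dt_ms
  n <- round(dur * fs)
  grid_t <- (seq_len(n) - 1L) / fs

  mod <- modulate_rates(list(mean = params$mve_interval_mean,
                             sd = params$mve_interval_cv *
                               params$mve_interval_mean),
                        protocol, duration = dur, dt = dt_ms,
                        seed = derive_seed(params$seed, 7L))

  # unitary Poisson process
  n_uni <- stats::rpois(1L, params$unitary_rate * dur)
  uni_times <- sort(stats::runif(n_uni, 0, dur))

  # multivesicular renewal process
  mve_times <- draw_mve_times(params, mod, dur)

  sh <- params$unitary_shape
  # template on the trace grid (coarse grids decimate a 1 ms dense build)
  if (dt_ms <= 1) {
    tmpl_grid <- make_unitary_template(sh$rise_10_90, sh$decay_tau, dt = dt_ms,
                                       duration = 5 * sh$decay_tau)
  } else {
    dense <- make_unitary_template(sh$rise_10_90, sh$decay_tau, dt = 1,
                                   duration = 5 * sh$decay_tau)
    tmpl_grid <- dense[seq(1L, length(dense), by = round(dt_ms))]
  }
  # fixed 1 ms template for clean per-event peak computation
  tmpl <- make_unitary_template(sh$rise_10_90, sh$decay_tau, dt = 1,
                                duration = 5 * sh$decay_tau)
  unit_charge_pC <- sum(tmpl_grid) * dt_ms * 1e-3  # pA * ms -> pC

  amp_ramp <- function(t_s) {
    r <- params$rundown_amp_ramp
    if (r <= 0) rep(1, length(t_s)) else pmin(1, 1 - 3 * r + r * t_s / 60)
  }

  # assemble all quanta as (time, amplitude) impulses
  q_time <- q_amp <- numeric(0)
  ev_rows <- list()
  draw_amp <- function(k, t_s) {
    # truncated-Gaussian amplitudes above the visibility floor
    if (sh$amplitude_sd > 0) {
      p0 <- stats::pnorm(sh$amplitude_floor, sh$amplitude_mean, sh$amplitude_sd)
      a <- stats::qnorm(stats::runif(k, p0, 1),
                        sh$amplitude_mean, sh$amplitude_sd)
    } else a <- rep(sh$amplitude_mean, k)
    a * amp_ramp(rep(t_s, k))
  }
  for (tt in uni_times) {
    a <- draw_amp(1L, tt)
    q_time <- c(q_time, tt); q_amp <- c(q_amp, a)
    ev_rows[[length(ev_rows) + 1L]] <-
      list(start_s = tt, class = "unitary", quanta = 1L,
           peak_pA = a, charge_pC = a * unit_charge_pC)
  }
  for (tt in mve_times) {
    k <- max(params$mve_quanta_floor,
             round(stats::rnorm(1L, params$mve_quanta_mean,
                                params$mve_quanta_sd)))
    shp <- params$intra_event_spacing_shape
    sp <- cumsum(c(0, stats::rgamma(k - 1L, shape = shp,
                                    rate = shp * 1000 /
                                      params$intra_event_spacing_mean)))
    a <- draw_amp(k, tt)
    q_time <- c(q_time, tt + sp); q_amp <- c(q_amp, a)
    # clean compound waveform peak on a 1 ms local grid
    loc <- seq(0, max(sp) + 5 * sh$decay_tau / 1000, by = 1e-3)
    wv <- numeric(length(loc))
    for (j in seq_len(k)) {
      idx <- which(loc >= sp[j])
      wv[idx] <- wv[idx] + a[j] * tmpl[pmin(length(tmpl),
                                            round((loc[idx] - sp[j]) * 1000) + 1L)]
    }
    ev_rows[[length(ev_rows) + 1L]] <-
      list(start_s = tt, class = "multivesicular", quanta = k,
           peak_pA = max(wv), charge_pC = sum(a) * unit_charge_pC)
  }

  current <- numeric(n)
  if (length(q_time)) {
    idx <- round(q_time * fs) + 1L
    keep <- idx >= 1L & idx <= n
    impulses <- numeric(n)
    tb <- tapply(q_amp[keep], idx[keep], sum)
    impulses[as.integer(names(tb))] <- tb
    full <- stats::convolve(impulses, rev(tmpl_grid), type = "open")
    current <- full[seq_len(n)]
  }
  if (params$recording_noise_sd > 0)
    current <- current + stats::rnorm(n, 0, params$recording_noise_sd)

  events <- if (length(ev_rows)) {
    dplyr::arrange(dplyr::bind_rows(lapply(ev_rows, tibble::as_tibble)),
                   .data$start_s)
  } else {
    tibble::tibble(start_s = numeric(0), class = character(0),
                   quanta = integer(0), peak_pA = numeric(0),
                   charge_pC = numeric(0))
  }

  structure(list(trace = tibble::tibble(time_s = grid_t, current_pA = current),
                 events = events, modulation = mod),
            class = "mvr_simulation",
            params = params, protocol = protocol, seed = params$seed,
            unit_charge_pC = unit_charge_pC)
}
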