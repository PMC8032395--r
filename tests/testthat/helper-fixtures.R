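# shared fixtures and small utilities for the suite

# 10-90% rise time measured directly on samples by linear interpolation of
# threshold crossings — independent of the package's internal measurement
rise_time_oracle <- function(w, dt_ms) {
  pk <- which.max(w)
  cross <- function(level) {
    i <- which(w[seq_len(pk)] >= level)[1]
    frac <- (level - w[i - 1]) / (w[i] - w[i - 1])
    (i - 2 + frac) * dt_ms
  }
  cross(0.9 * max(w)) - cross(0.1 * max(w))
}

# the canonical detection -> classification -> quantal-count recipe: mixture
# classes refined by the charge-ratio quantal count (an event is accepted as
# multivesicular when both the amplitude mixture and its quantal content say
# so), with a contamination-robust median unitary charge
run_event_pipeline <- function(sim) {
  det <- dplyr::filter(detect_events(sim$trace), charge_pC > 0)
  cl <- suppressWarnings(classify_events(det))
  uc <- stats::median(cl$charge_pC[cl$class == "unitary"])
  q <- quantal_count(cl$charge_pC, uc)
  cl$quanta <- q
  cl$class_final <- ifelse(cl$class == "multivesicular" & q >= 4,
                           "multivesicular", "unitary")
  list(events = cl, unitary_charge = uc)
}

# intervals from many stationary Erlang trials, pooled
pooled_erlang_intervals <- function(params, n_trials, seed0) {
  unlist(lapply(seq_len(n_trials), function(s) {
    diff(sample_erlang_events(params, flash = FALSE, seed = seed0 + s))
  }))
}

# standard error of a sample CV (delta method, near-Gaussian intervals)
cv_se <- function(cv, n) cv * sqrt(1 / (2 * (n - 1)) + cv^2 / (n - 1))
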