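#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of a pipeline run receives its own seed, derived
#' deterministically from one master seed and a stage index so that stages are
#' reproducible independently of each other. The scheme is a fixed affine
#' counter modulo a Mersenne prime, kept strictly below 2^31 so the result is
#' always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param stage integer stage counter (>= 0).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 0)
#' derive_seed(1, 1)
derive_seed <- function(master, stage = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(stage), length(stage) == 1L, stage >= 0)
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.numeric(master)) %% m)
  for (i in seq_len(stage + 1L)) {
    s <- (s * 48271 + 11) %% m
  }
  as.integer(s)
}

# internal: stop with a consistent message if a scalar parameter is bad
check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop(sprintf("`%s` must be a finite %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}

# internal: measured 10-90% rise time (ms) of a sampled waveform by linear
# interpolation of the threshold crossings on the rising limb
measure_rise_10_90 <- function(w, dt_ms) {
  pk_i <- which.max(w)
  pk <- w[pk_i]
  if (pk <= 0) return(NA_real_)
  rising <- w[seq_len(pk_i)]
  cross <- function(level) {
    i <- which(rising >= level)[1L]
    if (is.na(i) || i == 1L) return((i %||% 1L - 1L) * dt_ms)
    # linear interpolation between samples i-1 and i
    frac <- (level - rising[i - 1L]) / (rising[i] - rising[i - 1L])
    (i - 2L + frac) * dt_ms
  }
  cross(0.9 * pk) - cross(0.1 * pk)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
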