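#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a psychometric fit
#'
#' @param x a `psychometric_fit` from [fit_psychometric()].
#' @param ... unused.
#' @return A tibble with one row per parameter (`midpoint_log10`,
#'   `slope_sd_log10`, `threshold_75`).
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(term = c("midpoint_log10", "slope_sd_log10", "threshold_75"),
                 estimate = c(x$m, x$sd, x$threshold_75))
}

#' Glance at a psychometric fit
#'
#' @param x a `psychometric_fit`.
#' @param ... unused.
#' @return A one-row tibble: `threshold_75`, `extrapolated`, `r_squared`,
#'   `n_strengths`.
#' @export
glance.psychometric_fit <- function(x, ...) {
  fc <- x$data$fraction_correct
  tibble::tibble(threshold_75 = x$threshold_75,
                 extrapolated = x$extrapolated,
                 r_squared = r_squared(fc, x$fitted),
                 n_strengths = nrow(x$data))
}

#' Tidy a trained linear discriminant
#'
#' @param x a `discriminant_model` from [train_discriminant()].
#' @param ... unused.
#' @return A tibble with the discriminant waveform (`index`, `weight`).
#' @export
tidy.discriminant_model <- function(x, ...) {
  tibble::tibble(index = seq_along(x$D), weight = x$D)
}

#' Glance at a trained linear discriminant
#'
#' @param x a `discriminant_model`.
#' @param ... unused.
#' @return A one-row tibble with the projection summaries and the
#'   discriminability `d_prime = (mu_A - mu_B) / sqrt((sigma_A^2 + sigma_B^2)/2)`.
#' @export
glance.discriminant_model <- function(x, ...) {
  tibble::tibble(mu_A = x$mu_A, sigma_A = x$sigma_A,
                 mu_B = x$mu_B, sigma_B = x$sigma_B,
                 d_prime = (x$mu_A - x$mu_B) /
                   sqrt((x$sigma_A^2 + x$sigma_B^2) / 2),
                 n_train = x$n_train)
}
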