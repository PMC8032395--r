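#' Plot a synthetic recording with its ground-truth events
#'
#' @param object an `mvr_simulation` from [simulate_trace()].
#' @param window optional `c(from, to)` time window (s) to display.
#' @param ... unused.
#' @return A ggplot object: current trace with event starts marked by class.
#' @export
autoplot.mvr_simulation <- function(object, window = NULL, ...) {
  tr <- object$trace
  ev <- object$events
  if (!is.null(window)) {
    tr <- dplyr::filter(tr, .data$time_s >= window[1], .data$time_s <= window[2])
    ev <- dplyr::filter(ev, .data$start_s >= window[1], .data$start_s <= window[2])
  }
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$current_pA)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = ev,
                        ggplot2::aes(x = .data$start_s, y = .data$peak_pA,
                                     colour = .data$class),
                        shape = 17, size = 2) +
    ggplot2::labs(x = "time (s)", y = "transporter current (pA)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a peri-stimulus time histogram
#'
#' @param object an `mvr_psth` from [psth()].
#' @param ... unused.
#' @return A ggplot bar chart of counts per peri-stimulus bin.
#' @export
autoplot.mvr_psth <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$bin_mid_s, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$bin_start_s[1:2]) * 0.95,
                      fill = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = "time from stimulus onset (s)", y = "event count") +
    ggplot2::theme_minimal()
}

#' Plot an event-triggered average with standard-error band
#'
#' @param object an `mvr_eta` from [event_triggered_average()].
#' @param ... unused.
#' @return A ggplot line with +/- 2 SE ribbon; t = 0 is the event start.
#' @export
autoplot.mvr_eta <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag_s, y = .data$voltage_mv)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$voltage_mv - 2 * .data$se,
                                      ymax = .data$voltage_mv + 2 * .data$se),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time before event (s)", y = "stimulus voltage (mV)") +
    ggplot2::theme_minimal()
}

#' Plot a simulated rod response trace
#'
#' @param object a `rod_response` from [simulate_release_response()] or
#'   [simulate_photocurrent()].
#' @param ... unused.
#' @return A ggplot of the response with release-event times marked.
#' @export
autoplot.rod_response <- function(object, ...) {
  g <- ggplot2::ggplot(object$trace,
                       ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("%s response", attr(object, "model"))) +
    ggplot2::theme_minimal()
  if (length(object$event_times))
    g <- g + ggplot2::geom_rug(data = tibble::tibble(t = object$event_times),
                               ggplot2::aes(x = .data$t), inherit.aes = FALSE)
  g
}

#' Plot a psychometric function
#'
#' Fractions correct with binomial error bars on a log strength axis; the
#' ideal-photon-detector curve for the same pool size is overlaid for
#' reference.
#'
#' @param object a `psychometric_result` from [run_2afc()].
#' @param ideal overlay the ideal photon detector? Default `TRUE`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.psychometric_result <- function(object, ideal = TRUE, ...) {
  d <- tibble::as_tibble(object)
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$flash_strength,
                                       y = .data$fraction_correct)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$fraction_correct - .data$se,
      ymax = .data$fraction_correct + .data$se)) +
    ggplot2::geom_hline(yintercept = 0.75, linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0.45, 1)) +
    ggplot2::labs(x = "flash strength (Rh*/rod)", y = "fraction correct") +
    ggplot2::theme_minimal()
  if (ideal) {
    n_rods <- attr(object, "n_rods")
    xs <- exp(seq(log(min(d$flash_strength)), log(max(d$flash_strength)),
                  length.out = 200))
    g <- g + ggplot2::geom_line(
      data = tibble::tibble(flash_strength = xs,
                            fraction_correct = ideal_photon_detector(n_rods, xs)),
      linetype = 2, colour = "grey40")
  }
  g
}

#' Plot a fitted psychometric function
#'
#' @param object a `psychometric_fit` from [fit_psychometric()].
#' @param ... passed to [autoplot.psychometric_result()].
#' @return A ggplot with the cumulative-Gaussian fit and the 75% threshold.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  d <- object$data
  xs <- exp(seq(log(min(d$flash_strength)), log(max(d$flash_strength)),
                length.out = 200))
  curve_d <- tibble::tibble(
    flash_strength = xs,
    fraction_correct = 0.5 + 0.5 * stats::pnorm((log10(xs) - object$m) /
                                                  object$sd))
  base <- if (inherits(d, "psychometric_result")) {
    autoplot.psychometric_result(d, ...)
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$flash_strength,
                                    y = .data$fraction_correct)) +
      ggplot2::geom_point() + ggplot2::scale_x_log10() +
      ggplot2::theme_minimal()
  }
  base +
    ggplot2::geom_line(data = curve_d, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$threshold_75, linetype = 2,
                        colour = "steelblue")
}

#' Plot detection thresholds from a parameter sweep
#'
#' @param sweep a tibble from [sweep_thresholds()].
#' @param x name of the swept column for the x axis (e.g. `"E_f"`).
#' @param colour optional name of a second swept column mapped to colour.
#' @return A ggplot of threshold versus the swept parameter.
#' @export
plot_threshold_sweep <- function(sweep, x, colour = NULL) {
  stopifnot(is.data.frame(sweep), x %in% names(sweep))
  aes <- if (is.null(colour)) {
    ggplot2::aes(x = .data[[x]], y = .data$threshold_75)
  } else {
    ggplot2::aes(x = .data[[x]], y = .data$threshold_75,
                 colour = factor(.data[[colour]]))
  }
  ggplot2::ggplot(sweep, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "75%-correct threshold (Rh*/rod)",
                  colour = colour) +
    ggplot2::theme_minimal()
}
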