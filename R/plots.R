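#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a binned performance series over the stride cycle
#'
#' Points at bin centres with the option of overlaying the best
#' fixed-frequency Fourier fit.
#'
#' @param object a `binned_series`.
#' @param fit optional `fourier_fit` to overlay.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.binned_series <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$bin_center_pct,
                                    y = .data$value)) +
    ggplot2::geom_point(colour = "grey40") +
    ggplot2::labs(x = "Stride cycle (%)", y = "Value") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xx <- seq(0.005, 1, length.out = 400)
    curve <- tibble::tibble(bin_center_pct = 100 * xx,
                            value = predict(fit, xx))
    p <- p + ggplot2::geom_line(data = curve, colour = "#2166ac",
                                linewidth = 0.8)
  }
  p
}

#' Plot a frequency sweep with its permutation critical value
#'
#' @param object a `stride_sweep`.
#' @param null optional `perm_null`; drawn as a dashed line at the
#'   max-statistic 95% critical value.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.stride_sweep <- function(object, null = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_cps,
                                        y = .data$r2)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "Frequency (cycles per stride)",
                  y = expression(R^2)) +
    ggplot2::theme_minimal()
  if (!is.null(null)) {
    p <- p + ggplot2::geom_hline(yintercept = null$crit95,
                                 linetype = "dashed", colour = "grey30")
  }
  p
}

#' Plot a prevalence posterior with MAP and HPDI
#'
#' @param object a `prevalence_posterior`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.prevalence_posterior <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gamma, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_area(
      data = dplyr::filter(df, .data$gamma >= object$hpdi_low,
                           .data$gamma <= object$hpdi_high),
      alpha = 0.3, fill = "#2166ac"
    ) +
    ggplot2::geom_vline(xintercept = object$map, colour = "#b2182b") +
    ggplot2::labs(x = expression(gamma~(population~prevalence)),
                  y = "Posterior density") +
    ggplot2::theme_minimal()
}

#' Polar plot of participant phases
#'
#' @param phases tibble from [phase_sample()] (columns
#'   `participant_id`, `phase_rad`).
#' @return a ggplot in polar coordinates.
#' @export
plot_phase_clustering <- function(phases) {
  df <- dplyr::filter(phases, !is.na(.data$phase_rad))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase_rad %% (2 * pi))) +
    ggplot2::geom_histogram(breaks = seq(0, 2 * pi, length.out = 25),
                            fill = "#2166ac", colour = "white") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(
      limits = c(0, 2 * pi),
      breaks = seq(0, 3 * pi / 2, by = pi / 2),
      labels = c("0", "π/2", "π", "3π/2")
    ) +
    ggplot2::labs(x = "Phase (rad)", y = NULL) +
    ggplot2::theme_minimal()
}
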