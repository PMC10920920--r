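#' Mean resultant vector of a set of angles
#'
#' The first circular moment: `rbar` is the length of the average unit
#' vector (1 = perfect clustering, 0 = perfect dispersion) and
#' `mean_angle` its direction.
#'
#' @param angles radians.
#' @return list with `rbar` and `mean_angle` (radians in `(-pi, pi]`).
#' @export
mean_resultant <- function(angles) {
  if (!length(angles)) stop("no angles supplied", call. = FALSE)
  cbar <- mean(cos(angles))
  sbar <- mean(sin(angles))
  list(rbar = sqrt(cbar^2 + sbar^2),
       mean_angle = wrap_angle(atan2(sbar, cbar)))
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of phases is clustered rather than uniform on
#' the circle. The statistic is `Z = n * rbar^2`; the p-value uses the
#' standard second-order approximation
#' `p = exp(-Z) * (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2))`,
#' clamped to `(0, 1]`. Circular variance is reported as `1 - rbar`.
#'
#' @param angles radians; at least 4 (the approximation degrades below
#'   10, which triggers a warning).
#' @return a `rayleigh_test` object: list with `n`, `mean_angle`,
#'   `rbar`, `z`, `p`, `circ_variance`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 4) stop("Rayleigh test needs at least 4 angles", call. = FALSE)
  if (n < 10) warning("Rayleigh p-approximation is rough below n = 10",
                      call. = FALSE)
  mr <- mean_resultant(angles)
  z <- n * mr$rbar^2
  corr <- 1 + (2 * z - z^2) / (4 * n) -
    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2)
  p <- exp(-z) * corr
  if (!is.finite(p) || p <= 0) {
    # the series correction turns negative when z approaches n; fall
    # back to the standard exponential approximation, which stays
    # positive and monotone in that regime
    R <- n * mr$rbar
    p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  }
  out <- list(
    n = n, mean_angle = mr$mean_angle, rbar = mr$rbar, z = z,
    p = clamp(p, .Machine$double.xmin, 1),
    circ_variance = 1 - mr$rbar
  )
  class(out) <- "rayleigh_test"
  out
}

#' Express a series as relative change from its mean
#'
#' `(x - mean) / mean`, so curves from participants with different
#' baselines can be overlaid; the output has mean 0 and the amplitude
#' of any downstream fixed-frequency fit equals the raw amplitude
#' divided by the raw mean.
#'
#' @param values numeric vector with non-zero mean (`NA`s ignored for
#'   the mean).
#' @return numeric vector of relative changes.
#' @export
relative_change <- function(values) {
  m <- mean(values, na.rm = TRUE)
  if (!is.finite(m) || m == 0) {
    stop("relative change undefined for zero-mean series", call. = FALSE)
  }
  (values - m) / m
}

#' Collect 2-cps fit phases across participants
#'
#' For each participant's binned series, fits the fixed-frequency model
#' at `freq_cps` (default 2 cycles per stride) and retains the phase -
#' the input to the Rayleigh clustering test.
#'
#' @param series_by_participant named list of `binned_series`, one per
#'   participant.
#' @param freq_cps frequency at which to pull the phase.
#' @return tibble: `participant_id`, `freq_cps`, `phase_rad`,
#'   `amplitude`, `r2`.
#' @export
phase_sample <- function(series_by_participant, freq_cps = 2) {
  purrr::imap_dfr(series_by_participant, function(series, pid) {
    fit <- fit_fixed_frequency(series, freq_cps)
    tibble::tibble(
      participant_id = pid,
      freq_cps = freq_cps,
      phase_rad = if (is.null(fit)) NA_real_ else wrap_angle(fit$phi),
      amplitude = if (is.null(fit)) NA_real_ else fit$A,
      r2 = if (is.null(fit)) NA_real_ else fit$r2
    )
  })
}
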