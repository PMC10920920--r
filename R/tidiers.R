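#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.fourier_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a0", "a1", "b1", "A", "phi"),
    estimate = c(x$a0, x$a1, x$b1, x$A, x$phi)
  )
}

#' @export
glance.fourier_fit <- function(x, ...) {
  tibble::tibble(w = x$w, A = x$A, phi = x$phi, r2 = x$r2,
                 n_bins_used = x$n_bins_used)
}

#' @export
tidy.stride_sweep <- function(x, ...) {
  tibble::tibble(freq_cps = x$grid, r2 = x$r2)
}

#' @export
glance.stride_sweep <- function(x, ...) {
  tibble::tibble(best_freq_cps = x$best_freq,
                 best_r2 = max(x$r2, na.rm = TRUE),
                 amplitude = x$best_fit$A, phase_rad = x$best_fit$phi)
}

#' @export
tidy.perm_null <- function(x, ...) {
  tibble::tibble(freq_cps = x$grid, crit95_by_freq = x$crit95_by_freq)
}

#' @export
glance.perm_null <- function(x, ...) {
  tibble::tibble(crit95 = x$crit95, n_perm = x$n_perm, level = x$level)
}

#' @export
tidy.prevalence_posterior <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, density = x$density)
}

#' @export
glance.prevalence_posterior <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n, alpha = x$alpha, map = x$map,
                 hpdi_low = x$hpdi_low, hpdi_high = x$hpdi_high)
}

#' @export
glance.rayleigh_test <- function(x, ...) {
  tibble::tibble(n = x$n, mean_angle_rad = x$mean_angle, rbar = x$rbar,
                 z = x$z, p = x$p, circ_variance = x$circ_variance)
}

#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(threshold50 = x$threshold50, width_5_95 = x$width_5_95,
                 slope = x$slope, lapse = x$lapse,
                 converged = x$converged)
}

#' @export
print.fourier_fit <- function(x, ...) {
  cat(sprintf(
    "Fixed-frequency Fourier fit at %.2f cycles/stride\n", x$w))
  cat(sprintf("  a0 = %.4g, A = %.4g, phi = %.3f rad, R2 = %.3f (%d bins)\n",
              x$a0, x$A, x$phi, x$r2, x$n_bins_used))
  invisible(x)
}

#' @export
print.stride_sweep <- function(x, ...) {
  cat(sprintf(
    "Frequency sweep over %d frequencies (%.1f-%.1f cps)\n",
    length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  best: %.1f cps, R2 = %.3f\n", x$best_freq,
              max(x$r2, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.prevalence_posterior <- function(x, ...) {
  cat(sprintf(
    "Population prevalence: k = %d of n = %d at alpha = %.3g\n",
    x$k, x$n, x$alpha))
  cat(sprintf("  MAP = %.3f, 95%% HPDI [%.3f, %.3f]\n", x$map,
              x$hpdi_low, x$hpdi_high))
  invisible(x)
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf(
    "Rayleigh test of circular uniformity: n = %d\n", x$n))
  cat(sprintf("  Z = %.3f, p = %.4g, circular variance = %.3f\n",
              x$z, x$p, x$circ_variance))
  invisible(x)
}
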