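#' Maximum a posteriori estimate of population prevalence
#'
#' Given `k` of `n` participants significant at per-test false-positive
#' rate `alpha`, the probability a random participant tests positive is
#' `theta = (1 - gamma) * alpha + gamma * sensitivity` where `gamma` is
#' the population prevalence of true effects. Under a uniform prior on
#' `gamma`, the posterior mode is the clamped likelihood maximiser
#' `(k/n - alpha) / (sensitivity - alpha)`.
#'
#' @param k number of significant participants.
#' @param n number tested.
#' @param alpha per-test false-positive rate.
#' @param sensitivity assumed within-participant power (default 1).
#' @return the MAP prevalence in `[0, 1]`.
#' @export
prevalence_map <- function(k, n, alpha = 0.05, sensitivity = 1) {
  check_prevalence_args(k, n, alpha, sensitivity)
  clamp((k / n - alpha) / (sensitivity - alpha), 0, 1)
}

check_prevalence_args <- function(k, n, alpha, sensitivity) {
  if (!(is.numeric(k) && is.numeric(n) && k >= 0 && n >= 1 && k <= n &&
        k == round(k) && n == round(n))) {
    stop("k must be an integer in [0, n]", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)",
                                      call. = FALSE)
  if (!(sensitivity > alpha && sensitivity <= 1)) {
    stop("sensitivity must lie in (alpha, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Posterior distribution of population prevalence
#'
#' Evaluates the prevalence posterior on a regular grid over `[0, 1]`:
#' `density(gamma) proportional to theta^k * (1 - theta)^(n - k)` with
#' `theta = (1 - gamma) * alpha + gamma * sensitivity`, normalised by
#' trapezoidal integration under a uniform prior.
#'
#' @inheritParams prevalence_map
#' @param grid_n number of grid points (default 2001; fewer than 101
#'   warns).
#' @return a `prevalence_posterior` object: list with `k`, `n`, `alpha`,
#'   `sensitivity`, `gamma` (grid), `density`, `map` (grid argmax
#'   refined by the closed form), `hpdi_low`, `hpdi_high` (95%).
#' @export
prevalence_posterior <- function(k, n, alpha = 0.05, sensitivity = 1,
                                 grid_n = 2001) {
  check_prevalence_args(k, n, alpha, sensitivity)
  if (grid_n < 101) warning("coarse prevalence grid (< 101 points)",
                            call. = FALSE)
  gamma <- seq(0, 1, length.out = grid_n)
  theta <- (1 - gamma) * alpha + gamma * sensitivity
  logd <- k * log(theta) + (n - k) * log1p(-theta)
  logd[theta >= 1] <- if (k == n) 0 else -Inf
  d <- exp(logd - max(logd[is.finite(logd)]))
  # trapezoidal normalisation
  h <- gamma[2] - gamma[1]
  mass <- h * (sum(d) - (d[1] + d[grid_n]) / 2)
  d <- d / mass
  hp <- hpdi_grid(gamma, d, 0.95)
  out <- list(
    k = k, n = n, alpha = alpha, sensitivity = sensitivity,
    gamma = gamma, density = d,
    map = prevalence_map(k, n, alpha, sensitivity),
    map_grid = gamma[which.max(d)],
    hpdi_low = hp[1], hpdi_high = hp[2]
  )
  class(out) <- "prevalence_posterior"
  out
}

# shortest contiguous grid interval holding >= mass of the density
# (water-filling: scan all windows on the cumulative integral)
hpdi_grid <- function(x, d, mass = 0.95) {
  h <- x[2] - x[1]
  # cumulative trapezoidal integral
  cum <- c(0, cumsum((d[-1] + d[-length(d)]) / 2 * h))
  n <- length(x)
  best <- c(x[1], x[n])
  best_w <- Inf
  j <- 1
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j < n && cum[j] - cum[i] < mass) j <- j + 1
    if (cum[j] - cum[i] >= mass) {
      w <- x[j] - x[i]
      if (w < best_w) {
        best_w <- w
        best <- c(x[i], x[j])
      }
    }
  }
  best
}

#' Highest posterior density interval of a prevalence posterior
#'
#' Shortest contiguous interval of the posterior grid whose integrated
#' mass reaches the requested level. Warns when the density is
#' multimodal (the shortest contiguous interval is still returned).
#'
#' @param posterior a `prevalence_posterior`.
#' @param mass interval mass (default 0.95).
#' @return numeric vector `c(low, high)`.
#' @export
hpdi <- function(posterior, mass = 0.95) {
  stopifnot(inherits(posterior, "prevalence_posterior"))
  d <- posterior$density
  # modality check: sign changes of the smoothed derivative
  ds <- diff(d)
  flips <- sum(diff(sign(ds[ds != 0])) != 0)
  if (flips > 1) warning("multimodal posterior; HPDI is the shortest ",
                         "contiguous interval", call. = FALSE)
  hpdi_grid(posterior$gamma, d, mass)
}
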