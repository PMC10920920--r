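#' Maximum-likelihood cumulative-normal psychometric fit
#'
#' Fits `P(hit) = guess + (1 - guess - lapse) * Phi((c - mu) / sigma)`
#' to per-level hit counts by maximum likelihood, with the guess rate
#' fixed (0.5 for detection with a response floor) and the lapse rate
#' free up to `max_lapse`. Retains the 50% threshold (the intensity at
#' the midpoint between floor and ceiling, which is `mu`), the fit
#' width (intensity span between the 5th and 95th percentile points,
#' `sigma * (z_0.95 - z_0.05) = 3.2897 * sigma`), and the maximum slope
#' of the fitted curve.
#'
#' @param intensities tested intensity levels.
#' @param hits number of hits per level.
#' @param trials number of trials per level.
#' @param guess fixed guess rate.
#' @param max_lapse upper bound on the lapse rate.
#' @return a `psychometric_fit`: list with `mu`, `sigma`, `lapse`,
#'   `threshold50`, `width_5_95`, `slope`, `converged`, `flags`
#'   (character vector; e.g. threshold outside the tested range),
#'   `loglik`.
#' @export
fit_psychometric <- function(intensities, hits, trials, guess = 0.5,
                             max_lapse = 0.05) {
  stopifnot(length(intensities) == length(hits),
            length(hits) == length(trials))
  keep <- trials > 0
  intensities <- intensities[keep]
  hits <- hits[keep]
  trials <- trials[keep]
  if (length(unique(intensities)) < 4) {
    stop("need at least 4 distinct tested intensities", call. = FALSE)
  }
  nll <- function(par) {
    mu <- par[1]
    sigma <- exp(par[2])
    lapse <- max_lapse * stats::plogis(par[3])
    p <- guess + (1 - guess - lapse) *
      stats::pnorm((intensities - mu) / sigma)
    p <- clamp(p, 1e-9, 1 - 1e-9)
    -sum(hits * log(p) + (trials - hits) * log1p(-p))
  }
  span <- diff(range(intensities))
  start <- c(stats::weighted.mean(intensities, trials),
             log(max(span / 4, 1e-3)), 0)
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  mu <- opt$par[1]
  sigma <- exp(opt$par[2])
  lapse <- max_lapse * stats::plogis(opt$par[3])
  flags <- character()
  if (opt$convergence != 0) flags <- c(flags, "non-convergence")
  if (mu < min(intensities)) flags <- c(flags, "threshold below tested range")
  if (mu > max(intensities)) flags <- c(flags, "threshold above tested range")
  fit <- list(
    mu = mu, sigma = sigma, lapse = lapse, guess = guess,
    threshold50 = mu,
    width_5_95 = sigma * (stats::qnorm(0.95) - stats::qnorm(0.05)),
    slope = (1 - guess - lapse) * stats::dnorm(0) / sigma,
    converged = opt$convergence == 0,
    flags = flags,
    loglik = -opt$value
  )
  class(fit) <- "psychometric_fit"
  fit
}

#' Predicted hit probability from a psychometric fit
#'
#' @param object a `psychometric_fit`.
#' @param intensity intensities at which to evaluate the curve.
#' @param ... unused.
#' @return hit probabilities.
#' @export
predict.psychometric_fit <- function(object, intensity, ...) {
  object$guess + (1 - object$guess - object$lapse) *
    stats::pnorm((intensity - object$mu) / object$sigma)
}
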