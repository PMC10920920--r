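#' Fit a fixed-frequency first-order Fourier model to a binned series
#'
#' Fits `value ~ a0 + a1*cos(2*pi*w*x) + b1*sin(2*pi*w*x)` by ordinary
#' least squares, with `x = bin_center_pct / 100` the stride fraction in
#' `(0, 1]` and `w` the frequency in cycles per stride. For fixed `w`
#' this linear fit attains the same optimum as iterative non-linear
#' least squares on the amplitude-phase form `a0 + A*cos(2*pi*w*x + phi)`,
#' with `A = sqrt(a1^2 + b1^2)` and `phi = atan2(-b1, a1)`.
#'
#' Missing bins are dropped from the fit. `r2 = 1 - SSres / SStot`,
#' defined as 0 when the series is constant (`SStot = 0`).
#'
#' @param series a `binned_series` tibble from [bin_series()] (columns
#'   `bin_center_pct`, `value`).
#' @param w frequency in cycles per stride, > 0.
#' @return a `fourier_fit` object: list with `w`, `a0`, `a1`, `b1`, `A`,
#'   `phi`, `r2`, `n_bins_used`; or `NULL` when the design is
#'   rank-deficient at this frequency.
#' @export
fit_fixed_frequency <- function(series, w) {
  stopifnot(w > 0)
  ok <- !is.na(series$value)
  if (sum(ok) < 4) {
    stop("need at least 4 non-missing bins to fit", call. = FALSE)
  }
  x <- series$bin_center_pct[ok] / 100
  y <- series$value[ok]
  X <- cbind(1, cos(2 * pi * w * x), sin(2 * pi * w * x))
  qrX <- qr(X)
  if (qrX$rank < 3) return(NULL)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot <= .Machine$double.eps * length(y)) 0 else
    max(0, 1 - sum(res^2) / sstot)
  fit <- list(
    w = w, a0 = beta[1], a1 = beta[2], b1 = beta[3],
    A = sqrt(beta[2]^2 + beta[3]^2),
    phi = atan2(-beta[3], beta[2]),
    r2 = r2, n_bins_used = sum(ok)
  )
  class(fit) <- "fourier_fit"
  fit
}

#' Predict from a fixed-frequency Fourier fit
#'
#' @param object a `fourier_fit`.
#' @param x stride fractions in `(0, 1]`.
#' @param ... unused.
#' @return fitted values `a0 + A*cos(2*pi*w*x + phi)`.
#' @export
predict.fourier_fit <- function(object, x, ...) {
  object$a0 + object$A * cos(2 * pi * object$w * x + object$phi)
}

#' The standard sweep grid: 0.2 to 10 cycles per stride in 0.2 steps
#' @return numeric vector of 50 frequencies (exact multiples of 0.2).
#' @export
sweep_grid <- function() round(seq(0.2, 10, by = 0.2), 10)

#' Sweep the fixed-frequency Fourier fit across a frequency grid
#'
#' Fits the first-order Fourier model at every grid frequency and
#' retains the goodness of fit; the best frequency is the argmax of R2,
#' ties broken toward the lower frequency.
#'
#' @param series a `binned_series` tibble.
#' @param grid frequencies in cycles per stride.
#' @return a `stride_sweep` object: list with `grid`, `r2` (per
#'   frequency, `NA` where the fit was rank-deficient), `best_freq`,
#'   `best_fit` (a `fourier_fit`).
#' @export
sweep_frequencies <- function(series, grid = sweep_grid()) {
  fits <- purrr::map(grid, function(w) fit_fixed_frequency(series, w))
  r2 <- purrr::map_dbl(fits, function(f) if (is.null(f)) NA_real_ else f$r2)
  if (all(is.na(r2))) stop("all frequencies rank-deficient", call. = FALSE)
  best <- which.max(r2)  # first maximum = lowest frequency on ties
  out <- list(grid = grid, r2 = r2, best_freq = grid[best],
              best_fit = fits[[best]])
  class(out) <- "stride_sweep"
  out
}

# ---- fast vectorised sweep used by the permutation machinery ------------

# Orthonormal bases of the [1, cos, sin] design at each grid frequency,
# for a fixed set of bin centers (rows with data).
sweep_basis <- function(x, grid) {
  lapply(grid, function(w) {
    X <- cbind(1, cos(2 * pi * w * x), sin(2 * pi * w * x))
    qrX <- qr(X)
    if (qrX$rank < 3) return(NULL)
    qr.Q(qrX)
  })
}

# R2 of every column of Y (n_used x m) at every grid frequency.
# Returns a length(grid) x m matrix.
sweep_r2_matrix <- function(Y, basis) {
  n <- nrow(Y)
  css <- colSums(Y^2)
  sstot <- css - colSums(Y)^2 / n
  out <- matrix(NA_real_, length(basis), ncol(Y))
  for (k in seq_along(basis)) {
    Q <- basis[[k]]
    if (is.null(Q)) next
    ssres <- css - colSums(crossprod(Q, Y)^2)
    r2 <- 1 - ssres / sstot
    r2[sstot <= .Machine$double.eps * n] <- 0
    out[k, ] <- pmax(0, pmin(1, r2))
  }
  out
}
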