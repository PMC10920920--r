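#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic arithmetic stream-splitting so that each participant /
#' trial / permutation block gets an independent, reproducible seed while
#' everything remains a function of one master seed. Kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param ... one or more non-negative integer indices (participant, trial,
#'   ...) identifying the sub-stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1, all(idx >= 0))
  m <- 2147483647
  s <- as.double(master) %% m
  for (i in idx) {
    # LCG-style mix; multiplier from Park-Miller, offset keeps streams apart
    s <- (s * 48271 + as.double(i) + 1) %% m
  }
  as.integer(s)
}

#' Modified Akima piecewise-cubic Hermite interpolation
#'
#' Univariate interpolation with MATLAB's "makima" slope weights
#' w1 = |d2 - d1| + |d2 + d1|/2, which avoids the overshoot of plain cubic
#' splines and the flat-spot artefacts of classic Akima on equal slopes.
#' Points outside `range(x)` are extrapolated with the boundary cubic.
#'
#' @param x,y coordinates of data points; `x` strictly increasing, n >= 2.
#' @param xi points at which to interpolate.
#' @return numeric vector of interpolated values at `xi`.
#' @export
interp_makima <- function(x, y, xi) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2, !is.unsorted(x, strictly = TRUE))
  if (n == 2) { # degenerate: linear
    return(y[1] + (y[2] - y[1]) * (xi - x[1]) / (x[2] - x[1]))
  }
  h <- diff(x)
  d <- diff(y) / h
  # pad slopes by quadratic extrapolation (Akima's rule)
  dpad <- c(NA, NA, d, NA, NA)
  dpad[2] <- 2 * d[1] - d[2]
  dpad[1] <- 2 * dpad[2] - d[1]
  dpad[n + 2] <- 2 * d[n - 1] - d[n - 2]
  dpad[n + 3] <- 2 * dpad[n + 2] - d[n - 1]
  # makima weights; slope at point i uses dpad[i..i+3]
  t_ <- numeric(n)
  for (i in seq_len(n)) {
    d1 <- dpad[i]; d2 <- dpad[i + 1]; d3 <- dpad[i + 2]; d4 <- dpad[i + 3]
    w1 <- abs(d4 - d3) + abs(d4 + d3) / 2
    w2 <- abs(d2 - d1) + abs(d2 + d1) / 2
    t_[i] <- if (w1 + w2 == 0) (d2 + d3) / 2 else (w1 * d2 + w2 * d3) / (w1 + w2)
  }
  # evaluate Hermite cubics
  idx <- findInterval(xi, x, rightmost.closed = TRUE)
  idx <- clamp(idx, 1L, n - 1L)
  s <- (xi - x[idx]) / h[idx]
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y[idx] + h10 * h[idx] * t_[idx] + h01 * y[idx + 1] +
    h11 * h[idx] * t_[idx + 1]
}

# wrap an angle to (-pi, pi]
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# smallest absolute angular difference
angle_diff <- function(a, b) {
  abs(wrap_angle(a - b))
}
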