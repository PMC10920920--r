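# Shared fixture builders; everything is generated in code at test time.

# a noise-free walking trace with fixed step duration
clean_trace <- function(step_s = 0.59, trial_s = 9, frame_rate = 90,
                        amplitude = 0.025) {
  spec <- participant_spec(stride_duration_mean = 2 * step_s,
                           stride_duration_sd = 0, head_noise_sd = 0)
  cfg <- session_config(trial_duration = trial_s, frame_rate = frame_rate)
  spec$head_amplitude <- amplitude
  simulate_head_trace(spec, cfg, seed = 1, start_phase = 0.5)
}

# a tiled stride table covering [0, n_strides * stride_s]
tiled_strides <- function(stride_s = 1.2, n_strides = 7, offset = 0) {
  starts <- offset + stride_s * (seq_len(n_strides) - 1)
  tibble::tibble(
    start_s = starts,
    mid_s = starts + stride_s / 2,
    end_s = starts + stride_s,
    duration_s = stride_s
  )
}

# binned series straight from values on the standard 40-bin grid
series_from_values <- function(values) {
  n <- length(values)
  out <- tibble::tibble(
    bin = seq_len(n),
    bin_center_pct = (seq_len(n) - 0.5) * 100 / n,
    value = values,
    count = rep(10L, n)
  )
  class(out) <- c("binned_series", class(out))
  out
}

# von Mises sampler (Best & Fisher rejection scheme), for power checks
rvonmises <- function(n, mu = 0, kappa = 1) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      i <- i + 1
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
    }
  }
  out
}

# brute-force fixed-frequency fit: scan phase at `res` radians, solve the
# two remaining linear parameters exactly; independent of the OLS path
brute_force_fourier <- function(x, y, w, res = 1e-3) {
  phis <- seq(-pi, pi, by = res)
  best <- list(r2 = -Inf)
  sstot <- sum((y - mean(y))^2)
  n <- length(y)
  for (phi in phis) {
    c1 <- cos(2 * pi * w * x + phi)
    # OLS of y on [1, c1], closed form
    c1c <- c1 - mean(c1)
    yc <- y - mean(y)
    A <- sum(c1c * yc) / sum(c1c^2)
    a0 <- mean(y) - A * mean(c1)
    ssres <- sum((y - a0 - A * c1)^2)
    r2 <- 1 - ssres / sstot
    if (r2 > best$r2) best <- list(a0 = a0, A = A, phi = phi, r2 = r2)
  }
  # negative amplitude = phase off by pi; canonicalise
  if (best$A < 0) {
    best$A <- -best$A
    best$phi <- ((best$phi + pi + pi) %% (2 * pi)) - pi
  }
  best
}
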