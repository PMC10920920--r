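#' Remove the linear trend from a head-height trace
#'
#' Fits and subtracts a least-squares line over the whole trial, so slow
#' drift (posture change, tracking drift) does not bias trough prominence
#' downstream. The residual has mean zero by construction.
#'
#' @param trace data frame with columns `t` and `head_z`.
#' @return the trace with `head_z` replaced by the detrended height.
#' @export
detrend_height <- function(trace) {
  stopifnot(nrow(trace) >= 2)
  z <- trace$head_z
  if (stats::sd(z) == 0) {
    trace$head_z <- z - mean(z)
    return(trace)
  }
  fit <- stats::lm.fit(cbind(1, trace$t), z)
  trace$head_z <- unname(fit$residuals)
  trace
}

#' Detect footfall troughs in a detrended head-height trace
#'
#' Local minima of the vertical head position mark double-support stance
#' (both feet on the ground). A candidate minimum is kept when its
#' prominence is at least `min_prominence_frac` of the trial's robust
#' height range (5th-95th percentile) and it is at least
#' `min_separation_s` from any more prominent accepted trough.
#'
#' Candidates are found on a lightly smoothed copy of the trace (moving
#' average of width `smooth_s`), which stabilises trough positions
#' against measurement noise in the flat bottom of each arc; each
#' accepted trough is then refined to the vertex of a local quadratic
#' fit.
#'
#' @param trace data frame with `t` and detrended `head_z`.
#' @param min_prominence_frac fraction of the robust height range.
#' @param min_separation_s minimum spacing between troughs, seconds.
#' @param smooth_s moving-average width in seconds (0 disables).
#' @return integer vector of trough sample indices, in time order
#'   (possibly empty).
#' @export
detect_troughs <- function(trace, min_prominence_frac = 0.25,
                           min_separation_s = 0.35, smooth_s = 0.15) {
  z <- trace$head_z
  t <- trace$t
  n <- length(z)
  if (n < 3) return(integer())
  dt <- stats::median(diff(t))
  if (smooth_s > 0) {
    half <- max(1L, floor(smooth_s / dt / 2))
    cz <- cumsum(c(0, z))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    z <- (cz[hi + 1] - cz[lo]) / (hi - lo + 1)
  }
  rng <- diff(stats::quantile(z, c(0.05, 0.95), names = FALSE))
  if (rng <= 0) return(integer())
  min_prom <- min_prominence_frac * rng

  # candidate local minima (plateau-aware: strict drop on one side,
  # non-increase on the other)
  dz <- diff(z)
  cand <- which(dz[-1] > 0 & dz[-(n - 1)] <= 0) + 1L
  if (!length(cand)) return(integer())

  # prominence of a minimum: height to climb before reaching a lower point,
  # scanned left and right; the prominence is the smaller of the two walls
  prom <- vapply(cand, function(i) {
    left <- z[seq_len(i - 1)]
    right <- z[seq.int(i + 1, n)]
    lower_l <- which(rev(left) < z[i])
    wall_l <- if (length(lower_l)) {
      max(rev(left)[seq_len(lower_l[1] - 1)], z[i]) - z[i]
    } else max(left) - z[i]
    lower_r <- which(right < z[i])
    wall_r <- if (length(lower_r)) {
      max(right[seq_len(lower_r[1] - 1)], z[i]) - z[i]
    } else max(right) - z[i]
    min(wall_l, wall_r)
  }, numeric(1))

  keep <- cand[prom >= min_prom]
  pk <- prom[prom >= min_prom]
  if (!length(keep)) return(integer())

  # enforce separation, keeping the more prominent trough
  ord <- order(-pk)
  accepted <- integer()
  for (j in ord) {
    if (all(abs(t[keep[j]] - t[accepted]) >= min_separation_s)) {
      accepted <- c(accepted, keep[j])
    }
  }
  # refine each trough: on an effectively noise-free trace the raw
  # sample minimum is the best footfall estimate; under measurement
  # noise the vertex of a local quadratic on the smoothed trace is far
  # more stable in the flat bottom of the arc
  zraw <- trace$head_z
  # noise estimate from second differences (insensitive to the smooth
  # gait signal, whose per-frame curvature is tiny at 90 Hz)
  noise_est <- stats::mad(diff(zraw, differences = 2)) / sqrt(6)
  noisy <- noise_est > 0.02 * stats::sd(zraw)
  w <- max(2L, round(0.1 / dt))
  refined <- vapply(accepted, function(i) {
    lo <- max(1L, i - w)
    hi <- min(n, i + w)
    s <- seq.int(lo, hi)
    if (!noisy) return(s[which.min(zraw[s])])
    fit <- stats::lm.fit(cbind(1, s - i, (s - i)^2), z[s])
    a <- fit$coefficients[3]
    b <- fit$coefficients[2]
    if (!is.finite(a) || a <= 0) return(i)
    v <- i - b / (2 * a)
    as.integer(clamp(round(v), lo, hi))
  }, integer(1))
  sort(unique(refined))
}

#' Epoch strides from detected troughs
#'
#' A stride spans two consecutive steps: trough `i` to trough `i + 2`. In
#' the default overlapping mode strides advance by one trough, so every
#' event between the first and second-to-last troughs falls inside some
#' stride at full phase resolution; in non-overlapping mode strides tile
#' the trial (advance by two troughs).
#'
#' @param troughs trough indices from [detect_troughs()].
#' @param trace the data frame the indices refer to.
#' @param overlapping logical; overlapping stride enumeration (default).
#' @return tibble of strides: `start_s`, `mid_s`, `end_s`, `duration_s`
#'   (empty when fewer than 3 troughs).
#' @export
epoch_strides <- function(troughs, trace, overlapping = TRUE) {
  if (length(troughs) < 3) {
    return(tibble::tibble(start_s = numeric(), mid_s = numeric(),
                          end_s = numeric(), duration_s = numeric()))
  }
  tt <- trace$t[troughs]
  starts <- if (overlapping) seq_len(length(tt) - 2) else
    seq.int(1, length(tt) - 2, by = 2)
  tibble::tibble(
    start_s = tt[starts],
    mid_s = tt[starts + 1],
    end_s = tt[starts + 2],
    duration_s = tt[starts + 2] - tt[starts]
  )
}

#' Resample one stride onto the normalised 200-point phase grid
#'
#' Linearly interpolates the height samples of a stride onto 200 equally
#' spaced phase points (0.5% to 100% of cycle completion in steps of
#' 0.5%), so strides of different durations can be averaged.
#'
#' @param start_s,end_s stride boundaries in seconds.
#' @param trace data frame with `t` and `head_z`.
#' @return numeric vector of 200 interpolated heights, or `NULL` when the
#'   stride covers fewer than 4 raw samples.
#' @export
resample_stride <- function(start_s, end_s, trace) {
  sel <- trace$t >= start_s - 1e-9 & trace$t <= end_s + 1e-9
  if (sum(sel) < 4) return(NULL)
  grid <- start_s + (seq_len(200) / 200) * (end_s - start_s)
  stats::approx(trace$t[sel], trace$head_z[sel], xout = grid, rule = 2)$y
}

#' Quality-control one trial's head trace
#'
#' Rejects trials with wireless drop-out (any inter-sample gap longer
#' than 3 frame intervals), a flat signal (height range below an absolute
#' floor), implausible step durations (median outside `step_bounds`), or
#' too few troughs to epoch a stride.
#'
#' @param trace data frame with `t`, `head_z`.
#' @param troughs trough indices from [detect_troughs()].
#' @param frame_rate Hz of the nominal sampling grid.
#' @param min_height_range metres; absolute floor on the height range.
#' @param step_bounds plausible median step-duration interval, seconds.
#' @return list with `accept` (logical) and `reason` (`NA` if accepted).
#' @export
qc_trials <- function(trace, troughs, frame_rate = 90,
                      min_height_range = 0.005,
                      step_bounds = c(0.35, 1.0)) {
  if (any(!is.finite(trace$head_z))) {
    return(list(accept = FALSE, reason = "drop-out"))
  }
  gaps <- diff(trace$t)
  if (length(gaps) && max(gaps) > 3 / frame_rate) {
    return(list(accept = FALSE, reason = "drop-out"))
  }
  if (diff(range(trace$head_z)) < min_height_range) {
    return(list(accept = FALSE, reason = "flat signal"))
  }
  if (length(troughs) < 3) {
    return(list(accept = FALSE, reason = "too few troughs"))
  }
  med_step <- stats::median(diff(trace$t[troughs]))
  if (med_step < step_bounds[1] || med_step > step_bounds[2]) {
    return(list(accept = FALSE, reason = "implausible step duration"))
  }
  list(accept = TRUE, reason = NA_character_)
}

#' Extract strides from a frames table
#'
#' Runs the full gait stage per trial - detrend, trough detection, QC,
#' stride epoching - over a long frames table (one row per sample) and
#' returns all accepted strides plus a per-trial QC log.
#'
#' @param frames data frame with `participant_id`, `trial_id`, `t`,
#'   `head_z` (walking trials only; filter beforehand if needed).
#' @param overlapping stride enumeration mode, see [epoch_strides()].
#' @param min_prominence_frac,min_separation_s trough-detector settings.
#' @param frame_rate Hz, for the QC drop-out rule.
#' @return list of two tibbles: `strides` (`participant_id`, `trial_id`,
#'   `start_s`, `mid_s`, `end_s`, `duration_s`) and `qc` (`participant_id`,
#'   `trial_id`, `accept`, `reason`).
#' @export
extract_gait <- function(frames, overlapping = TRUE,
                         min_prominence_frac = 0.25,
                         min_separation_s = 0.35, frame_rate = 90) {
  frames |>
    dplyr::group_by(.data$participant_id, .data$trial_id) |>
    dplyr::group_map(function(tr, key) {
      if (all(is.finite(tr$head_z))) {
        tr <- detrend_height(tr)
        troughs <- detect_troughs(tr, min_prominence_frac,
                                  min_separation_s)
      } else {
        troughs <- integer()
      }
      qc <- qc_trials(tr, troughs, frame_rate)
      strides <- if (qc$accept) epoch_strides(troughs, tr, overlapping) else
        epoch_strides(integer(), tr)
      list(
        strides = dplyr::bind_cols(key[rep(1, nrow(strides)), ], strides),
        qc = dplyr::bind_cols(key, tibble::tibble(accept = qc$accept,
                                                  reason = qc$reason))
      )
    }) |>
    purrr::transpose() |>
    purrr::map(dplyr::bind_rows)
}
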