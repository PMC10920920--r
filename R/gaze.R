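#' Detect blinks from gaze-direction discontinuities
#'
#' A blink shows up in eye-tracker output as a large frame-to-frame jump
#' in the recorded gaze-direction coordinates. Frames where the absolute
#' change on any axis exceeds `jump_threshold` seed blink intervals;
#' seeds closer together than `merge_window_s` are merged into one
#' interval.
#'
#' A blink displaces the trace and then returns it: a departure jump
#' followed, within `max_blink_s`, by an opposite-signed return jump on
#' the dominant axis is treated as one interval spanning both.
#' Remaining intervals closer together than `merge_window_s` are merged.
#'
#' @param trace data frame with `t` and `gaze_dir_x`, `gaze_dir_y`,
#'   `gaze_dir_z` columns (any subset of axes present is used).
#' @param jump_threshold metres; per-axis discontinuity threshold.
#' @param merge_window_s merge window for adjacent intervals, seconds.
#' @param max_blink_s longest departure/return pair to join, seconds.
#' @return tibble of blink intervals: `start_s`, `end_s` (zero rows when
#'   none found).
#' @export
detect_blinks <- function(trace, jump_threshold = 0.8,
                          merge_window_s = 0.1, max_blink_s = 0.5) {
  stopifnot(nrow(trace) >= 2)
  axes <- intersect(c("gaze_dir_x", "gaze_dir_y", "gaze_dir_z"),
                    names(trace))
  stopifnot(length(axes) >= 1)
  deltas <- sapply(axes, function(a) diff(trace[[a]]))
  if (is.null(dim(deltas))) deltas <- matrix(deltas, ncol = length(axes))
  deltas[is.na(deltas)] <- 0
  mag <- apply(abs(deltas), 1, max)
  idx <- which(mag > jump_threshold)
  if (!length(idx)) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  }
  # signed change on the dominant axis of each jump
  sgn <- vapply(idx, function(i) {
    sign(deltas[i, which.max(abs(deltas[i, ]))])
  }, numeric(1))

  starts <- numeric()
  ends <- numeric()
  k <- 1
  while (k <= length(idx)) {
    if (k < length(idx) &&
        sgn[k + 1] == -sgn[k] &&
        trace$t[idx[k + 1] + 1] - trace$t[idx[k]] <= max_blink_s) {
      starts <- c(starts, trace$t[idx[k]])
      ends <- c(ends, trace$t[idx[k + 1] + 1])
      k <- k + 2
    } else {
      starts <- c(starts, trace$t[idx[k]])
      ends <- c(ends, trace$t[idx[k] + 1])
      k <- k + 1
    }
  }
  # merge adjacent intervals within the window
  keep_s <- starts[1]
  keep_e <- ends[1]
  for (k in seq_along(starts)[-1]) {
    if (starts[k] - keep_e[length(keep_e)] <= merge_window_s) {
      keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], ends[k])
    } else {
      keep_s <- c(keep_s, starts[k])
      keep_e <- c(keep_e, ends[k])
    }
  }
  tibble::tibble(start_s = keep_s, end_s = keep_e)
}

#' Repair blink intervals by modified Akima interpolation
#'
#' Replaces samples from `pad_s` before each blink to `pad_s` after it
#' with a modified Akima piecewise-cubic interpolation through the
#' surrounding valid samples, applied to every gaze column present
#' (origin and direction, all axes). Overlapping padded windows merge
#' into one repair span; a blink at the trace edge is filled with the
#' nearest valid value and flagged.
#'
#' @param trace data frame with `t` and gaze columns
#'   (`gaze_origin_*`, `gaze_dir_*`).
#' @param intervals blink intervals from [detect_blinks()].
#' @param pad_s padding around each interval, seconds.
#' @return the repaired trace, with attribute `repaired` (logical mask
#'   of replaced samples) and `edge_blinks` (number of intervals that
#'   touched a trace edge).
#' @export
interpolate_blinks <- function(trace, intervals, pad_s = 0.2) {
  cols <- grep("^gaze_(origin|dir)_[xyz]$", names(trace), value = TRUE)
  stopifnot(length(cols) >= 1)
  if (!nrow(intervals)) {
    attr(trace, "repaired") <- rep(FALSE, nrow(trace))
    attr(trace, "edge_blinks") <- 0L
    return(trace)
  }
  t <- trace$t
  bad <- rep(FALSE, length(t))
  for (k in seq_len(nrow(intervals))) {
    bad <- bad | (t >= intervals$start_s[k] - pad_s &
                    t <= intervals$end_s[k] + pad_s)
  }
  edge <- sum(intervals$start_s - pad_s <= t[1] |
                intervals$end_s + pad_s >= t[length(t)])
  good <- !bad
  if (sum(good) < 2) {
    stop("not enough valid samples to interpolate blinks", call. = FALSE)
  }
  for (col in cols) {
    y <- trace[[col]]
    yi <- interp_makima(t[good], y[good], t[bad])
    # nearest-valid extrapolation outside the valid support
    yi[t[bad] < t[good][1]] <- y[good][1]
    yi[t[bad] > t[good][sum(good)]] <- y[good][sum(good)]
    y[bad] <- yi
    trace[[col]] <- y
  }
  attr(trace, "repaired") <- bad
  attr(trace, "edge_blinks") <- edge
  trace
}

#' Exclude targets presented while gaze was off-target
#'
#' Computes the angle between the gaze direction and the target
#' direction (both taken from the eye at target onset) and drops events
#' whose offset exceeds the angular limit. Events with missing gaze
#' (e.g. an unrepaired blink at onset) are dropped with their own
#' reason.
#'
#' @param events data frame with gaze-direction columns `gaze_dir_x`,
#'   `gaze_dir_y`, `gaze_dir_z` and target-direction columns
#'   `target_dir_x`, `target_dir_y`, `target_dir_z` at onset.
#' @param limit_deg angular exclusion limit in degrees of visual angle.
#' @return the events with `offset_deg`, `keep` (logical) and
#'   `drop_reason` columns appended.
#' @export
exclude_offtarget_events <- function(events, limit_deg = 12.1) {
  g <- as.matrix(events[c("gaze_dir_x", "gaze_dir_y", "gaze_dir_z")])
  v <- as.matrix(events[c("target_dir_x", "target_dir_y", "target_dir_z")])
  dot <- rowSums(g * v)
  cosang <- dot / (sqrt(rowSums(g^2)) * sqrt(rowSums(v^2)))
  offset <- acos(clamp(cosang, -1, 1)) * 180 / pi
  missing <- !is.finite(offset)
  keep <- !missing & offset <= limit_deg
  events$offset_deg <- offset
  events$keep <- keep
  events$drop_reason <- dplyr::case_when(
    missing ~ "missing gaze at onset",
    !keep ~ "gaze off target",
    TRUE ~ NA_character_
  )
  events
}

#' Gaze-origin variability over the stride cycle
#'
#' Mechanical-artefact control: if footfall impacts jolted the headset,
#' the pupil-origin coordinates would be more variable at specific
#' stride phases. Each trial's origin coordinates are linearly
#' detrended, every frame is assigned a stride phase, and the per-bin
#' standard deviation of each coordinate (pooled across strides and
#' trials) is returned.
#'
#' @param frames data frame with `participant_id`, `trial_id`, `t` and
#'   `gaze_origin_x`, `gaze_origin_y`, `gaze_origin_z`.
#' @param strides stride table from [extract_gait()].
#' @param n_bins number of phase bins.
#' @return tibble: `bin`, `bin_center_pct`, `sd_x`, `sd_y`, `sd_z`,
#'   `sd_pooled` (root mean variance across axes), `count`.
#' @export
gaze_origin_variability <- function(frames, strides, n_bins = 40) {
  if (!nrow(strides)) stop("empty stride set", call. = FALSE)
  detr <- function(t, y) {
    stats::lm.fit(cbind(1, t), y)$residuals
  }
  fr <- frames |>
    dplyr::group_by(.data$participant_id, .data$trial_id) |>
    dplyr::mutate(
      gaze_origin_x = detr(.data$t, .data$gaze_origin_x),
      gaze_origin_y = detr(.data$t, .data$gaze_origin_y),
      gaze_origin_z = detr(.data$t, .data$gaze_origin_z)
    ) |>
    dplyr::ungroup()
  assigned <- assign_stride_phase(fr, strides, onset_col = "t")
  assigned <- dplyr::filter(assigned, !is.na(.data$phase_pct))
  width <- 100 / n_bins
  assigned$bin <- pmin(pmax(ceiling(assigned$phase_pct / width), 1L),
                       n_bins)
  assigned |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      sd_x = stats::sd(.data$gaze_origin_x),
      sd_y = stats::sd(.data$gaze_origin_y),
      sd_z = stats::sd(.data$gaze_origin_z),
      sd_pooled = sqrt(mean(c(stats::var(.data$gaze_origin_x),
                              stats::var(.data$gaze_origin_y),
                              stats::var(.data$gaze_origin_z)))),
      count = dplyr::n()
    ) |>
    dplyr::mutate(bin_center_pct = (.data$bin - 0.5) * width,
                  .after = "bin")
}
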