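#' Assign behavioural events to stride-cycle phase percentiles
#'
#' Each event is placed in the stride containing it and given the
#' percentile (in `(0, 100]`) at which it occurred. Stride intervals are
#' treated as half-open `(start, end]`: an event exactly at a footfall
#' belongs to the stride that footfall ends (phase 100).
#'
#' When the supplied strides overlap (step-advancing enumeration from
#' [epoch_strides()]), assignment uses the tiled subset anchored at the
#' first trough (strides 1, 3, 5, ...), so that phases cover the full
#' `(0, 100]` range and uniform probing yields a flat phase histogram;
#' overlapping strides double-cover every instant, which would otherwise
#' fold all phases into half the cycle.
#'
#' @param events data frame with an onset column (default `onset_s`) and,
#'   for multi-trial data, `participant_id` and `trial_id` columns
#'   matching `strides`.
#' @param strides stride table from [extract_gait()] or
#'   [epoch_strides()].
#' @param onset_col name of the event-time column.
#' @return the events with `phase_pct` (NA when dropped), `stride_start_s`,
#'   `stride_end_s` and `drop_reason` columns appended; row count is
#'   preserved (conservation).
#' @export
assign_stride_phase <- function(events, strides, onset_col = "onset_s") {
  keys <- intersect(c("participant_id", "trial_id"),
                    intersect(names(events), names(strides)))
  assign_one <- function(ev, st) {
    st <- dplyr::arrange(st, .data$start_s)
    if (nrow(st) >= 2 && any(st$start_s[-1] < st$end_s[-nrow(st)] - 1e-12)) {
      st <- st[seq.int(1, nrow(st), by = 2), , drop = FALSE]  # tile overlaps
    }
    e <- ev[[onset_col]]
    # half-open (start, end]: index of the stride whose interval holds e
    idx <- findInterval(e, st$start_s, left.open = TRUE)
    ok <- idx >= 1 & idx <= nrow(st)
    inside <- ok
    inside[ok] <- e[ok] <= st$end_s[idx[ok]] + 1e-12
    reason <- dplyr::case_when(
      e <= st$start_s[1] ~ "before first stride",
      e > st$end_s[nrow(st)] ~ "after last stride",
      !inside ~ "in stride gap",
      TRUE ~ NA_character_
    )
    phase <- rep(NA_real_, length(e))
    s0 <- st$start_s[idx[inside]]
    s1 <- st$end_s[idx[inside]]
    phase[inside] <- 100 * (e[inside] - s0) / (s1 - s0)
    ev$phase_pct <- phase
    ev$stride_start_s <- ifelse(inside, st$start_s[replace(idx, !inside, 1)],
                                NA_real_)
    ev$stride_end_s <- ifelse(inside, st$end_s[replace(idx, !inside, 1)],
                              NA_real_)
    ev$drop_reason <- reason
    ev
  }
  if (!length(keys)) return(assign_one(events, strides))
  events |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(ev, key) {
      st <- dplyr::inner_join(key, strides, by = keys)
      if (!nrow(st)) {
        ev$phase_pct <- NA_real_
        ev$stride_start_s <- NA_real_
        ev$stride_end_s <- NA_real_
        ev$drop_reason <- "no accepted strides"
        return(ev)
      }
      assign_one(ev, st)
    }) |>
    dplyr::ungroup()
}

#' Bin a phase-assigned measure over the stride cycle
#'
#' Averages (or counts) events within `n_bins` linearly spaced,
#' non-overlapping bins covering `(0, 100]` of the stride cycle.
#' `statistic = "mean"` gives the per-bin mean of `value` (hit rate for
#' 0/1 outcomes, mean RT for reaction times); `statistic = "density"`
#' gives per-bin event counts normalised to mean 1 across bins. Empty
#' bins yield `NA` values and are dropped by the Fourier fit rather than
#' imputed.
#'
#' @param data data frame of phase-assigned events.
#' @param value unquoted column with the per-event measure (ignored for
#'   `statistic = "density"`).
#' @param n_bins number of bins (20, 40, 100 and 200 are conventional).
#' @param statistic `"mean"` or `"density"`.
#' @param phase unquoted phase column (percent in `(0, 100]`).
#' @return a `binned_series` tibble: `bin`, `bin_center_pct`, `value`,
#'   `count`.
#' @export
bin_series <- function(data, value = NULL, n_bins = 40,
                       statistic = c("mean", "density"),
                       phase = phase_pct) {
  statistic <- match.arg(statistic)
  ph <- dplyr::pull(dplyr::filter(data, !is.na({{ phase }})), {{ phase }})
  width <- 100 / n_bins
  idx <- pmin(pmax(ceiling(ph / width), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  if (statistic == "mean") {
    v <- dplyr::pull(dplyr::filter(data, !is.na({{ phase }})), {{ value }})
    keep <- !is.na(v)
    sums <- rep(0, n_bins)
    if (any(keep)) {
      s <- rowsum(v[keep], idx[keep])
      sums[as.integer(rownames(s))] <- s[, 1]
    }
    nv <- tabulate(idx[keep], nbins = n_bins)
    vals <- ifelse(nv > 0, sums / nv, NA_real_)
    counts <- nv
    if (mean(nv > 0) < 0.8) {
      warning("fewer than 80% of bins contain events", call. = FALSE)
    }
  } else {
    vals <- if (sum(counts) > 0) counts / mean(counts) else
      rep(NA_real_, n_bins)
  }
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    bin_center_pct = (seq_len(n_bins) - 0.5) * width,
    value = as.numeric(vals),
    count = as.integer(counts)
  )
  class(out) <- c("binned_series", class(out))
  attr(out, "statistic") <- statistic
  out
}

#' Response-onset likelihood over the stride cycle
#'
#' Phase-assigns manual response onsets (not target onsets) and bins
#' them as a normalised density (mean 1 across bins) - the frequency of
#' self-initiated responses at each stride phase.
#'
#' @param responses data frame with a `press_onset_s` column (plus
#'   `participant_id` / `trial_id` keys when applicable).
#' @param strides stride table, as for [assign_stride_phase()].
#' @param n_bins number of phase bins.
#' @return a `binned_series` tibble.
#' @export
response_likelihood_series <- function(responses, strides, n_bins = 40) {
  assigned <- assign_stride_phase(responses, strides,
                                  onset_col = "press_onset_s")
  bin_series(assigned, n_bins = n_bins, statistic = "density")
}

#' Clock-time control series
#'
#' Folds events modulo consecutive fixed-length epochs of trial time
#' (default 1 s) instead of stride phase, and bins them identically. The
#' stride-locked and clock-locked sweeps can then be compared: a genuine
#' stride-phase modulation survives stride-locking but smears out under
#' clock-locking whenever stride duration varies.
#'
#' @param events data frame with trial-relative timestamps.
#' @param value unquoted measure column (ignored for density).
#' @param time_col name of the timestamp column.
#' @param epoch_length_s epoch length in seconds.
#' @param n_bins,statistic as in [bin_series()].
#' @return a `binned_series` tibble; `bin_center_pct` is percent of the
#'   epoch.
#' @export
clocktime_series <- function(events, value = NULL, time_col = "onset_s",
                             epoch_length_s = 1.0, n_bins = 40,
                             statistic = c("mean", "density")) {
  statistic <- match.arg(statistic)
  ev <- events
  tt <- ev[[time_col]] %% epoch_length_s
  ev$.clock_pct <- ifelse(tt == 0, 100, 100 * tt / epoch_length_s)
  bin_series(ev, value = {{ value }}, n_bins = n_bins,
             statistic = statistic, phase = .clock_pct)
}
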