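#' Group-level binned series averaged over participants
#'
#' Bins each participant's events separately and averages the per-bin
#' values across participants with equal weight (participants with an
#' empty bin simply drop out of that bin's average). This is the series
#' the group-level sweep and permutation null operate on.
#'
#' @param events phase-assigned events with `participant_id` and
#'   `phase_pct` columns.
#' @param value unquoted measure column (ignored for density).
#' @param n_bins number of phase bins.
#' @param statistic `"mean"` or `"density"`.
#' @return a `binned_series` tibble; `count` is the total event count
#'   per bin across participants.
#' @export
group_series <- function(events, value = NULL, n_bins = 40,
                         statistic = c("mean", "density")) {
  statistic <- match.arg(statistic)
  per <- events |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_map(function(ev, key) {
      suppressWarnings(
        bin_series(ev, value = {{ value }}, n_bins = n_bins,
                   statistic = statistic)
      )
    })
  vals <- sapply(per, function(b) b$value)
  counts <- sapply(per, function(b) b$count)
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    bin_center_pct = (seq_len(n_bins) - 0.5) * (100 / n_bins),
    value = rowMeans(vals, na.rm = TRUE),
    count = as.integer(rowSums(counts))
  )
  out$value[is.nan(out$value)] <- NA_real_
  class(out) <- c("binned_series", class(out))
  attr(out, "statistic") <- statistic
  out
}

#' Max-statistic permutation null for the frequency sweep
#'
#' Shuffles outcome values across events within each participant (phase
#' labels fixed - exactly equivalent to shuffling the events' bin
#' allocations without replacement), rebuilds the binned series, re-runs
#' the frequency sweep, and retains the maximum R2 across the grid per
#' permutation. The 95th percentile of these maxima is the family-wise
#' critical value over the whole frequency grid. The observed data never
#' enter the null.
#'
#' For `statistic = "density"` the shuffle permutes phase assignments
#' against a fixed event count, which leaves a density series invariant;
#' following the bin-allocation reading of the shuffle, density nulls
#' instead redraw each event's bin uniformly (destroying any phase
#' structure while conserving the event count).
#'
#' @param events phase-assigned events with `participant_id`,
#'   `phase_pct` and (for mean statistics) the measure column.
#' @param value unquoted measure column.
#' @param n_bins number of phase bins.
#' @param statistic `"mean"` or `"density"`.
#' @param grid frequency grid, cycles per stride.
#' @param n_perm number of permutations (1000 is the reference setting;
#'   fewer than 100 gives an unstable tail and triggers a warning).
#' @param seed integer seed for the shuffles.
#' @param level `"group"` (average the permuted per-participant series,
#'   as for [group_series()]) or `"participant"` (events must belong to
#'   one participant).
#' @return a `perm_null` object: list with `grid`, `null_r2`
#'   (`n_perm` x `length(grid)`), `maxstat`, `crit95`, `n_perm`, `seed`.
#' @export
permutation_null <- function(events, value = NULL, n_bins = 40,
                             statistic = c("mean", "density"),
                             grid = sweep_grid(), n_perm = 1000,
                             seed = 1L,
                             level = c("group", "participant")) {
  statistic <- match.arg(statistic)
  level <- match.arg(level)
  if (n_perm < 100) {
    warning("n_perm < 100 gives an unstable null tail", call. = FALSE)
  }
  ev <- dplyr::filter(events, !is.na(.data$phase_pct))
  if (statistic == "mean") {
    ev <- dplyr::filter(ev, !is.na({{ value }}))
  }
  if (level == "participant" &&
      length(unique(ev$participant_id)) > 1) {
    stop("participant-level null requires events from one participant",
         call. = FALSE)
  }
  width <- 100 / n_bins
  by_p <- split(
    data.frame(
      b = pmin(pmax(ceiling(ev$phase_pct / width), 1L), n_bins),
      v = if (statistic == "mean") dplyr::pull(ev, {{ value }}) else 1
    ),
    ev$participant_id
  )

  set.seed(seed)
  sum_vals <- matrix(0, n_bins, n_perm)   # running sums across participants
  sum_nz <- matrix(0L, n_bins, n_perm)    # participants contributing per bin
  for (d in by_p) {
    n_i <- nrow(d)
    counts <- tabulate(d$b, nbins = n_bins)
    if (statistic == "mean") {
      perm <- vapply(seq_len(n_perm),
                     function(j) d$v[sample.int(n_i)], numeric(n_i))
      s <- matrix(0, n_bins, n_perm)
      rs <- rowsum(perm, d$b)
      s[as.integer(rownames(rs)), ] <- rs
      binned <- sweep(s, 1, pmax(counts, 1L), "/")
      has <- counts > 0
    } else {
      # density null: redraw bins uniformly, conserve the event count
      binned <- vapply(seq_len(n_perm), function(j) {
        cb <- tabulate(sample.int(n_bins, n_i, replace = TRUE),
                       nbins = n_bins)
        cb / mean(cb)
      }, numeric(n_bins))
      has <- rep(TRUE, n_bins)
    }
    sum_vals[has, ] <- sum_vals[has, ] + binned[has, , drop = FALSE]
    sum_nz[has, ] <- sum_nz[has, ] + 1L
  }
  Y <- sum_vals / pmax(sum_nz, 1L)
  used <- rowSums(sum_nz) > 0
  if (sum(used) < 4) stop("too few occupied bins for the null sweep",
                          call. = FALSE)
  x <- ((seq_len(n_bins) - 0.5) * width / 100)[used]
  basis <- sweep_basis(x, grid)
  null_r2 <- t(sweep_r2_matrix(Y[used, , drop = FALSE], basis))
  maxstat <- apply(null_r2, 1, max, na.rm = TRUE)
  out <- list(
    grid = grid, null_r2 = null_r2, maxstat = maxstat,
    crit95 = stats::quantile(maxstat, 0.95, names = FALSE),
    crit95_by_freq = apply(null_r2, 2, stats::quantile, probs = 0.95,
                           na.rm = TRUE, names = FALSE),
    n_perm = n_perm, seed = seed, level = level
  )
  class(out) <- "perm_null"
  out
}

#' Frequency ranges where the observed sweep beats the permutation null
#'
#' Maximal runs of contiguous grid frequencies whose observed R2
#' strictly exceeds the max-statistic critical value.
#'
#' @param sweep a `stride_sweep`.
#' @param null a `perm_null` on the same grid.
#' @return tibble with `low_cps`, `high_cps` (zero rows when nothing is
#'   significant).
#' @export
significant_ranges <- function(sweep, null) {
  stopifnot(isTRUE(all.equal(sweep$grid, null$grid)))
  sig <- !is.na(sweep$r2) & sweep$r2 > null$crit95
  if (!any(sig)) {
    return(tibble::tibble(low_cps = numeric(), high_cps = numeric()))
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(low_cps = sweep$grid[starts[keep]],
                 high_cps = sweep$grid[ends[keep]])
}

band_of <- function(best_freq, significant) {
  dplyr::case_when(
    !significant ~ "none",
    best_freq >= 1.5 & best_freq <= 2.5 ~ "two_cps",
    best_freq >= 3.5 & best_freq <= 4.5 ~ "four_cps",
    best_freq > 5 ~ "high",
    TRUE ~ "none"
  )
}

#' Participant-level oscillation test
#'
#' Compares one participant's observed sweep to their own permutation
#' null. Under the default max-statistic rule the participant is
#' significant when the observed maximum R2 over the grid exceeds the
#' 95th percentile of the null maxima; the per-frequency alternative
#' declares significance when any frequency beats its own per-frequency
#' 95th percentile. The frequency band is derived from the best
#' frequency: `two_cps` for 1.5-2.5, `four_cps` for 3.5-4.5, `high`
#' above 5 cps.
#'
#' @param sweep the participant's `stride_sweep`.
#' @param null the participant's `perm_null` (built with
#'   `level = "participant"`).
#' @param participant_id,measure identifiers carried into the result.
#' @param method `"maxstat"` (default) or `"per_frequency"`.
#' @return one-row tibble: `participant_id`, `measure`, `best_freq`,
#'   `best_r2`, `significant`, `band`.
#' @export
participant_test <- function(sweep, null, participant_id = NA_character_,
                             measure = NA_character_,
                             method = c("maxstat", "per_frequency")) {
  method <- match.arg(method)
  obs_max <- max(sweep$r2, na.rm = TRUE)
  significant <- if (method == "maxstat") {
    obs_max > null$crit95
  } else {
    any(sweep$r2 > null$crit95_by_freq, na.rm = TRUE)
  }
  tibble::tibble(
    participant_id = participant_id,
    measure = measure,
    best_freq = sweep$best_freq,
    best_r2 = obs_max,
    significant = significant,
    band = band_of(sweep$best_freq, significant)
  )
}

#' Cohort summary of participant-level results
#'
#' Counts significant participants per frequency band and measure
#' (`k` of `n`), and reports cross-measure frequency stability: among
#' participants significant on at least two measures, the fraction whose
#' band agrees across all their significant measures.
#'
#' @param results row-bound [participant_test()] tibbles.
#' @return list with `band_counts` (tibble: `measure`, `band`, `k`, `n`)
#'   and `cross_measure_agreement` (fraction, `NA` when undefined).
#' @export
cohort_summary <- function(results) {
  n_per_measure <- results |>
    dplyr::count(.data$measure, name = "n")
  band_counts <- results |>
    dplyr::filter(.data$significant) |>
    dplyr::count(.data$measure, .data$band, name = "k") |>
    dplyr::right_join(
      tidyr::expand_grid(measure = unique(results$measure),
                         band = c("two_cps", "four_cps", "high")),
      by = c("measure", "band")
    ) |>
    dplyr::mutate(k = dplyr::coalesce(.data$k, 0L)) |>
    dplyr::left_join(n_per_measure, by = "measure") |>
    dplyr::arrange(.data$measure, .data$band)

  multi <- results |>
    dplyr::filter(.data$significant) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(agree = dplyr::n_distinct(.data$band) == 1)
  agreement <- if (nrow(multi)) mean(multi$agree) else NA_real_
  list(band_counts = band_counts, cross_measure_agreement = agreement)
}

#' Correlate stride duration with oscillation metrics
#'
#' Rank (Spearman) correlations of per-participant stride duration
#' against (a) R2 at 2 cps, (b) R2 at 4 cps, (c) best frequency in
#' cycles per stride, and (d) best frequency in Hz
#' (`cps / stride_duration_s`). A fixed cycles-per-stride rhythm across
#' participants shows up as a negative duration-vs-Hz correlation by
#' construction, with no duration-vs-cps correlation.
#'
#' @param metrics tibble with `participant_id`, `stride_duration_s`,
#'   `best_freq_cps`, `r2_at_2cps`, `r2_at_4cps`.
#' @return tibble: `metric`, `rho`, `p_value`, `n`.
#' @export
stride_duration_correlation <- function(metrics) {
  if (nrow(metrics) < 5) {
    stop("need at least 5 participants for stride-duration correlations",
         call. = FALSE)
  }
  if (stats::sd(metrics$stride_duration_s) == 0) {
    warning("constant stride durations: correlations undefined",
            call. = FALSE)
    return(tibble::tibble(
      metric = c("r2_at_2cps", "r2_at_4cps", "best_freq_cps",
                 "best_freq_hz"),
      rho = NA_real_, p_value = NA_real_, n = nrow(metrics)
    ))
  }
  dur <- metrics$stride_duration_s
  cols <- list(
    r2_at_2cps = metrics$r2_at_2cps,
    r2_at_4cps = metrics$r2_at_4cps,
    best_freq_cps = metrics$best_freq_cps,
    best_freq_hz = metrics$best_freq_cps / dur
  )
  purrr::imap_dfr(cols, function(v, nm) {
    ct <- suppressWarnings(
      stats::cor.test(dur, v, method = "spearman", exact = FALSE)
    )
    tibble::tibble(metric = nm, rho = unname(ct$estimate),
                   p_value = ct$p.value, n = length(dur))
  })
}
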