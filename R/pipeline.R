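#' Analysis-pipeline configuration
#'
#' Settings shared by every stage of [run_pipeline()]: phase bin count,
#' frequency grid, permutation count, per-test alpha, stride enumeration
#' mode, participant-level test rule, and the master seed.
#'
#' @param n_bins phase bins for the binned series.
#' @param grid frequency grid in cycles per stride.
#' @param n_perm permutations per null (1000 reference, 200 fast).
#' @param alpha per-test false-positive rate.
#' @param seed integer master seed.
#' @param measures subset of `"accuracy"`, `"rt"`,
#'   `"response_likelihood"` to analyse.
#' @param participant_method `"maxstat"` or `"per_frequency"`, see
#'   [participant_test()].
#' @param overlapping stride enumeration mode, see [epoch_strides()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_bins = 40, grid = sweep_grid(),
                            n_perm = 1000, alpha = 0.05, seed = 1L,
                            measures = c("accuracy", "rt",
                                         "response_likelihood"),
                            participant_method = "maxstat",
                            overlapping = TRUE) {
  cfg <- list(
    n_bins = n_bins, grid = grid, n_perm = n_perm, alpha = alpha,
    seed = as.integer(seed), measures = measures,
    participant_method = participant_method, overlapping = overlapping
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every invariant and returns all violations rather than
#' stopping at the first.
#'
#' @param config a `pipeline_config`.
#' @return character vector of violations; empty when the config is ok.
#' @export
validate_config <- function(config) {
  v <- character()
  if (!config$n_bins %in% c(20, 40, 100, 200)) {
    v <- c(v, "n_bins must be one of 20, 40, 100, 200")
  }
  if (length(config$grid) < 1 || any(config$grid <= 0) ||
      is.unsorted(config$grid, strictly = TRUE)) {
    v <- c(v, "grid must be a strictly increasing vector of positive frequencies")
  }
  if (config$n_perm < 1) v <- c(v, "n_perm must be >= 1")
  if (config$alpha <= 0 || config$alpha >= 1) {
    v <- c(v, "alpha must lie in (0, 1)")
  }
  if (!all(config$measures %in% c("accuracy", "rt",
                                  "response_likelihood"))) {
    v <- c(v, "unknown measure name")
  }
  if (!config$participant_method %in% c("maxstat", "per_frequency")) {
    v <- c(v, "participant_method must be 'maxstat' or 'per_frequency'")
  }
  v
}

session_schemas <- list(
  frames = c("participant_id", "trial_id", "condition", "t",
             "head_x", "head_y", "head_z"),
  targets = c("participant_id", "trial_id", "onset_s", "intensity",
              "quantile_level", "outcome", "rt_s"),
  responses = c("participant_id", "trial_id", "press_onset_s")
)

#' Read a session dataset from disk
#'
#' Loads `frames.csv`, `targets.csv` and `responses.csv` from a cohort
#' directory (as written by [generate_cohort()]), checking each file's
#' schema. Missing required columns raise an error naming the column;
#' unknown extra columns are kept with a warning.
#'
#' @param dir directory containing the session files.
#' @return list of tibbles: `frames`, `targets`, `responses`.
#' @export
read_session <- function(dir) {
  out <- purrr::imap(session_schemas, function(cols, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) {
      stop("missing session file: ", path, call. = FALSE)
    }
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      stop(name, ".csv lacks required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(names(df), cols)
    if (length(extra)) {
      warning(name, ".csv has unknown column(s), ignored: ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
    df
  })
  names(out) <- names(session_schemas)
  out
}

#' Write an analysis report as JSON
#'
#' @param report a report list from [run_pipeline()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

measure_events <- function(measure, targets, responses, strides) {
  if (measure == "response_likelihood") {
    assigned <- assign_stride_phase(responses, strides,
                                    onset_col = "press_onset_s")
    assigned$value <- 1
    list(events = assigned, statistic = "density")
  } else {
    assigned <- assign_stride_phase(targets, strides)
    assigned$value <- if (measure == "accuracy") {
      as.numeric(assigned$outcome == "hit")
    } else {
      assigned$rt_s  # NA for misses; RT series uses hits only
    }
    list(events = assigned, statistic = "mean")
  }
}

#' Run the full stride-cycle analysis pipeline
#'
#' Executes gait extraction, stride-phase projection, group- and
#' participant-level frequency sweeps with max-statistic permutation
#' nulls, Bayesian population prevalence per frequency band, and the
#' Rayleigh phase-clustering test, and assembles a machine-readable
#' report. All randomness derives from `config$seed`, so the same
#' session and config give a byte-identical report.
#'
#' @param session a directory path (read via [read_session()]) or a
#'   list with `frames`, `targets`, `responses` tibbles.
#' @param config a [pipeline_config()].
#' @return the report: a named list with `config`, `counts` (event
#'   conservation per stage), `gait`, `group` (per measure: sweep,
#'   critical value, significant ranges), `participants`,
#'   `band_counts`, `cross_measure_agreement`, `prevalence`,
#'   `rayleigh`.
#' @export
run_pipeline <- function(session, config = pipeline_config()) {
  violations <- validate_config(config)
  if (length(violations)) {
    stop("invalid pipeline config: ", paste(violations, collapse = "; "),
         call. = FALSE)
  }
  if (is.character(session)) session <- read_session(session)
  frames <- dplyr::filter(session$frames, .data$condition == "walk")
  targets <- session$targets
  responses <- session$responses

  gait <- extract_gait(frames, overlapping = config$overlapping)
  strides <- gait$strides

  pids <- sort(unique(targets$participant_id))
  report <- list(
    config = list(
      n_bins = config$n_bins, grid = config$grid, n_perm = config$n_perm,
      alpha = config$alpha, seed = config$seed,
      measures = config$measures,
      participant_method = config$participant_method,
      overlapping = config$overlapping
    ),
    counts = list(
      n_trials = nrow(dplyr::distinct(frames, .data$participant_id,
                                      .data$trial_id)),
      n_trials_accepted = sum(gait$qc$accept),
      n_strides = nrow(strides),
      n_targets = nrow(targets),
      n_responses = nrow(responses)
    ),
    gait = list(
      stride_duration_mean_s = mean(strides$duration_s),
      stride_duration_sd_s = stats::sd(strides$duration_s)
    )
  )

  group <- list()
  participants <- list()
  phases <- list()
  for (m in config$measures) {
    me <- measure_events(m, targets, responses, strides)
    ev <- me$events
    n_assigned <- sum(!is.na(ev$phase_pct))
    gs <- group_series(ev, value = value, n_bins = config$n_bins,
                       statistic = me$statistic)
    sw <- sweep_frequencies(gs, config$grid)
    null <- permutation_null(
      ev, value = value, n_bins = config$n_bins,
      statistic = me$statistic, grid = config$grid,
      n_perm = config$n_perm,
      seed = derive_seed(config$seed, match(m, config$measures)),
      level = "group"
    )
    ranges <- significant_ranges(sw, null)
    group[[m]] <- list(
      n_events = nrow(ev), n_assigned = n_assigned,
      n_dropped = nrow(ev) - n_assigned,
      best_freq_cps = sw$best_freq, best_r2 = max(sw$r2, na.rm = TRUE),
      crit95 = null$crit95,
      r2_by_freq = sw$r2,
      significant_ranges = ranges
    )

    ptests <- purrr::map_dfr(pids, function(pid) {
      evp <- dplyr::filter(ev, .data$participant_id == pid,
                           !is.na(.data$phase_pct))
      ps <- suppressWarnings(
        bin_series(evp, value = value, n_bins = config$n_bins,
                   statistic = me$statistic)
      )
      psw <- sweep_frequencies(ps, config$grid)
      pnull <- permutation_null(
        evp, value = value, n_bins = config$n_bins,
        statistic = me$statistic, grid = config$grid,
        n_perm = config$n_perm,
        seed = derive_seed(config$seed, match(m, config$measures),
                           match(pid, pids)),
        level = "participant"
      )
      res <- participant_test(psw, pnull, participant_id = pid,
                              measure = m,
                              method = config$participant_method)
      fit2 <- fit_fixed_frequency(ps, 2)
      res$phase_2cps_rad <- if (is.null(fit2)) NA_real_ else
        wrap_angle(fit2$phi)
      res
    })
    participants[[m]] <- ptests

    sig2 <- dplyr::filter(ptests, .data$significant,
                          .data$band == "two_cps")
    phases[[m]] <- if (nrow(sig2) >= 4) {
      rt <- suppressWarnings(rayleigh_test(sig2$phase_2cps_rad))
      list(n = rt$n, mean_angle_rad = rt$mean_angle, rbar = rt$rbar,
           z = rt$z, p = rt$p, circ_variance = rt$circ_variance)
    } else {
      list(n = nrow(sig2), note = "too few phase-clustered participants")
    }
  }

  all_results <- dplyr::bind_rows(participants)
  summ <- cohort_summary(all_results)
  prevalence <- purrr::pmap(summ$band_counts, function(measure, band, k,
                                                       n) {
    post <- prevalence_posterior(k, n, config$alpha)
    list(measure = measure, band = band, k = k, n = n,
         map = post$map, hpdi = c(post$hpdi_low, post$hpdi_high))
  })
  # any-frequency prevalence per measure
  any_freq <- all_results |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(k = sum(.data$significant), n = dplyr::n())
  prevalence_any <- purrr::pmap(any_freq, function(measure, k, n) {
    post <- prevalence_posterior(k, n, config$alpha)
    list(measure = measure, band = "any", k = k, n = n,
         map = post$map, hpdi = c(post$hpdi_low, post$hpdi_high))
  })

  report$group <- group
  report$participants <- all_results
  report$band_counts <- summ$band_counts
  report$cross_measure_agreement <- summ$cross_measure_agreement
  report$prevalence <- c(prevalence, prevalence_any)
  report$rayleigh <- phases
  report
}
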