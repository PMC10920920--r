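#' Simulate a vertical head-position trace for one walking trial
#'
#' Builds the head trajectory as a concatenation of per-step raised-cosine
#' arcs: one trough per footfall (two troughs per stride), so step-duration
#' jitter accumulates across the trial as it does in real gait. Step
#' durations are drawn from Normal(stride_duration_mean / 2,
#' stride_duration_sd / sqrt(2)), truncated positive. The trial starts
#' mid-swing, so the first trough falls half a step after onset. Gaussian
#' measurement noise and an optional slow linear drift are added, and the
#' walker advances along x at the configured walking speed.
#'
#' The returned tibble carries the generator's ground truth: a
#' `true_phase_pct` column (stride phase of every sample relative to the
#' most recent true footfall, percent of the two-step stride) and a
#' `truth` attribute with the exact footfall times.
#'
#' @param spec a [participant_spec()].
#' @param config a [session_config()].
#' @param seed integer seed for this trial's randomness.
#' @param drift_slope metres per second of slow linear drift in head
#'   height (default 0).
#' @param head_height baseline head height in metres.
#' @param start_phase stride fraction already completed at trial onset.
#'   The default `NULL` draws it uniformly, as recording onset is
#'   independent of footfall timing in real walking; a fixed value
#'   gives a fully deterministic construction when the step-duration SD
#'   and noise are zero.
#' @return a tibble with columns `t`, `head_x`, `head_y`, `head_z`,
#'   `true_phase_pct`; attribute `truth` is a list with `boundaries` (all
#'   step boundaries, including the pre-trial one) and `troughs` (footfall
#'   times inside the trial).
#' @export
simulate_head_trace <- function(spec, config, seed = 1L, drift_slope = 0,
                                head_height = 1.6, start_phase = NULL) {
  validate_participant_spec(spec)
  validate_session_config(config)
  set.seed(seed)
  dur <- config$trial_duration
  dt <- 1 / config$frame_rate
  step_mu <- spec$stride_duration_mean / 2
  step_sd <- spec$stride_duration_sd / sqrt(2)

  draw_step <- function() {
    repeat {
      s <- stats::rnorm(1, step_mu, step_sd)
      if (s > 0.05) return(s)
    }
  }
  # step boundaries; trial onset falls at a random (or fixed) fraction
  # of a full stride, so trials are not gait-phase-locked
  u <- if (is.null(start_phase)) stats::runif(1) else start_phase
  stopifnot(u >= 0, u < 1)
  s1 <- draw_step()
  s2 <- draw_step()
  b <- cumsum(c(-u * (s1 + s2), s1, s2))
  while (b[length(b)] < dur + 3 * spec$stride_duration_mean) {
    b <- c(b, b[length(b)] + draw_step())
  }
  t <- seq(0, dur - dt / 2, by = dt)
  step_idx <- findInterval(t, b)
  u <- (t - b[step_idx]) / (b[step_idx + 1] - b[step_idx])
  z <- head_height + spec$head_amplitude * (1 - cos(2 * pi * u)) +
    drift_slope * t +
    stats::rnorm(length(t), 0, spec$head_noise_sd)

  # true stride phase: strides tile the trial from the first step
  # boundary (two steps each); each sample's phase is its position in
  # the containing tiled stride
  stride_idx <- step_idx - (step_idx - 1) %% 2
  phase <- 100 * (t - b[stride_idx]) / (b[stride_idx + 2] - b[stride_idx])

  out <- tibble::tibble(
    t = t,
    head_x = config$walking_speed * t,
    head_y = stats::rnorm(length(t), 0, spec$head_noise_sd),
    head_z = z,
    true_phase_pct = phase
  )
  attr(out, "truth") <- list(
    boundaries = b,
    troughs = b[b > 0 & b <= dur]
  )
  out
}

#' Ground-truth stride phase of an event time
#'
#' Strides tile the trial from the first step boundary (two steps per
#' stride); each event's phase is its position within the containing
#' tiled stride, as a fraction in `[0, 1)`.
#'
#' @param t_event event times, seconds (trial-relative).
#' @param boundaries true step-boundary times from the generator.
#' @return numeric vector of stride-phase fractions; `NA` outside coverage.
#' @export
true_stride_phase <- function(t_event, boundaries) {
  j <- findInterval(t_event, boundaries)
  j <- j - (j - 1) %% 2   # snap to the tiled stride's starting boundary
  ok <- j >= 1 & (j + 2) <= length(boundaries)
  out <- rep(NA_real_, length(t_event))
  out[ok] <- (t_event[ok] - boundaries[j[ok]]) /
    (boundaries[j[ok] + 2] - boundaries[j[ok]])
  out
}

#' Schedule target onsets for one trial
#'
#' Anchor times receive independent uniform jitter of +/- `target_jitter`
#' seconds; each target is then withheld with probability
#' `withhold_probability`. The minimum inter-target interval is enforced
#' by pushing any onset closer than `min_iti` to its predecessor forward
#' to `predecessor + min_iti` (with anchors at least `min_iti` apart this
#' never moves an onset beyond `anchor + target_jitter`).
#'
#' @param config a [session_config()].
#' @param seed integer seed.
#' @return sorted numeric vector of onset times (possibly empty).
#' @export
schedule_targets <- function(config, seed = 1L) {
  validate_session_config(config)
  set.seed(seed)
  a <- config$target_anchors
  n <- length(a)
  if (n == 0) return(numeric())
  on <- a + stats::runif(n, -config$target_jitter, config$target_jitter)
  for (i in seq_len(n)[-1]) {
    if (on[i] - on[i - 1] < config$min_iti) on[i] <- on[i - 1] + config$min_iti
  }
  keep <- stats::runif(n) >= config$withhold_probability
  sort(on[keep])
}

#' Hit probability of the simulated cumulative-normal observer
#'
#' `P(hit) = guess + (1 - guess - lapse) * Phi((intensity - threshold) / width)`
#' with guess 0.5 and lapse 0.01, matching the staircase's assumed floor
#' and lapse rate.
#'
#' @param intensity grayscale intensity in `[0.4, 1]`.
#' @param spec a [participant_spec()] supplying `observer_threshold` and
#'   `observer_width`.
#' @param guess,lapse psychometric floor and lapse rate.
#' @return hit probabilities.
#' @export
observer_hit_prob <- function(intensity, spec, guess = 0.5, lapse = 0.01) {
  if (any(intensity < 0.4 - 1e-9 | intensity > 1 + 1e-9)) {
    stop("intensity must lie in [0.4, 1]", call. = FALSE)
  }
  guess + (1 - guess - lapse) *
    stats::pnorm((intensity - spec$observer_threshold) / spec$observer_width)
}

#' Simulate observer responses at given intensities
#'
#' Bernoulli draws from [observer_hit_prob()]. Uses the current RNG state.
#'
#' @inheritParams observer_hit_prob
#' @return integer vector of 0/1 outcomes.
#' @export
simulate_staircase_observer <- function(intensity, spec, guess = 0.5,
                                        lapse = 0.01) {
  p <- observer_hit_prob(intensity, spec, guess, lapse)
  as.integer(stats::runif(length(p)) < p)
}

#' Simulate behavioural outcomes for scheduled targets
#'
#' Hits are Bernoulli with probability
#' `base_hit_rate + osc_amplitude_acc * cos(2*pi*f*x + phase)` where `x`
#' is the true stride-phase fraction of the target onset. Hits get a
#' reaction time `base_rt - osc_amplitude_rt * cos(2*pi*f*x + phase)`
#' plus Gaussian noise, truncated at 0.15 s, and emit a response event at
#' `onset + rt`. Misses produce no response.
#'
#' @param onsets target onset times, seconds.
#' @param spec a [participant_spec()].
#' @param phase_frac stride-phase fraction in `[0, 1)` for each onset
#'   (e.g. from [true_stride_phase()]).
#' @param seed integer seed.
#' @return list with `targets` (tibble: `onset_s`, `phase_frac`,
#'   `outcome`, `rt_s`) and `responses` (tibble: `press_onset_s`).
#' @export
simulate_outcomes <- function(onsets, spec, phase_frac, seed = 1L) {
  stopifnot(length(onsets) == length(phase_frac))
  validate_participant_spec(spec)
  set.seed(seed)
  n <- length(onsets)
  if (n == 0) {
    return(list(
      targets = tibble::tibble(onset_s = numeric(), phase_frac = numeric(),
                               outcome = character(), rt_s = numeric()),
      responses = tibble::tibble(press_onset_s = numeric())
    ))
  }
  osc <- cos(2 * pi * spec$osc_frequency * phase_frac + spec$osc_phase)
  p_hit <- spec$base_hit_rate + spec$osc_amplitude_acc * osc
  hit <- stats::runif(n) < p_hit
  rt <- rep(NA_real_, n)
  if (any(hit)) {
    rt_raw <- spec$base_rt - spec$osc_amplitude_rt * osc[hit] +
      stats::rnorm(sum(hit), 0, spec$rt_noise_sd)
    rt[hit] <- pmax(rt_raw, 0.15)
  }
  targets <- tibble::tibble(
    onset_s = onsets,
    phase_frac = phase_frac,
    outcome = ifelse(hit, "hit", "miss"),
    rt_s = rt
  )
  responses <- tibble::tibble(press_onset_s = onsets[hit] + rt[hit])
  list(targets = targets, responses = responses)
}

#' Event-level cohort simulator
#'
#' Fast path for analysis-scale simulations: skips the head trace and
#' draws each target's stride phase directly (uniform over the stride, as
#' random probing guarantees), then applies the outcome model of
#' [simulate_outcomes()]. Useful for parameter-recovery and calibration
#' studies where gait extraction itself is not under test.
#'
#' @param specs list of [participant_spec()] objects.
#' @param targets_per_participant number of targets per participant.
#' @param seed integer master seed; participants get derived sub-seeds.
#' @return tibble with `participant_id`, `phase_pct` (percent in (0,100]),
#'   `hit` (0/1), `rt_s` (NA for misses).
#' @export
simulate_cohort_events <- function(specs, targets_per_participant = 900,
                                   seed = 1L) {
  purrr::imap_dfr(specs, function(spec, i) {
    set.seed(derive_seed(seed, i))
    x <- stats::runif(targets_per_participant)
    osc <- cos(2 * pi * spec$osc_frequency * x + spec$osc_phase)
    hit <- as.integer(stats::runif(targets_per_participant) <
                        spec$base_hit_rate + spec$osc_amplitude_acc * osc)
    rt <- spec$base_rt - spec$osc_amplitude_rt * osc +
      stats::rnorm(targets_per_participant, 0, spec$rt_noise_sd)
    rt <- pmax(rt, 0.15)
    rt[hit == 0] <- NA_real_
    tibble::tibble(
      participant_id = spec$participant_id,
      phase_pct = 100 * x,
      hit = hit,
      rt_s = rt
    )
  })
}

#' Generate a complete synthetic cohort on disk
#'
#' Simulates every participant and trial of a session and writes the
#' standard session files: `frames.csv` (head trace), `targets.csv`,
#' `responses.csv`, `manifest.json` (config echo and seed) and
#' `ground_truth.json` (every participant's true parameters and per-trial
#' footfall times). Regeneration with the same seed is byte-identical.
#' Stationary trials have flat head height plus noise and no stride
#' structure.
#'
#' @param config a [session_config()].
#' @param specs list of [participant_spec()], length `n_participants`;
#'   defaults to [sample_participant_specs()] under the config seed.
#' @param dir output directory (created if needed).
#' @return invisibly, the list of file paths written.
#' @export
generate_cohort <- function(config, specs = NULL, dir) {
  validate_session_config(config)
  if (is.null(specs)) {
    specs <- sample_participant_specs(config$n_participants,
                                      seed = config$rng_seed)
  }
  stopifnot(length(specs) == config$n_participants)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  frames <- vector("list", 0)
  targets <- vector("list", 0)
  responses <- vector("list", 0)
  truth_troughs <- list()

  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    pid <- spec$participant_id
    troughs_p <- list()
    for (tr in seq_len(config$n_walking_trials)) {
      trace <- simulate_head_trace(spec, config,
                                   seed = derive_seed(config$rng_seed, i, tr))
      truth <- attr(trace, "truth")
      onsets <- schedule_targets(config,
                                 seed = derive_seed(config$rng_seed, i, tr, 1))
      x <- true_stride_phase(onsets, truth$boundaries)
      out <- simulate_outcomes(onsets, spec, x,
                               seed = derive_seed(config$rng_seed, i, tr, 2))
      trial_id <- sprintf("w%03d", tr)
      frames[[length(frames) + 1]] <- dplyr::mutate(
        trace[c("t", "head_x", "head_y", "head_z")],
        participant_id = pid, trial_id = trial_id, condition = "walk",
        .before = 1
      )
      targets[[length(targets) + 1]] <- dplyr::mutate(
        out$targets,
        participant_id = pid, trial_id = trial_id, .before = 1,
        intensity = spec$observer_threshold, quantile_level = 0L
      )
      responses[[length(responses) + 1]] <- dplyr::mutate(
        out$responses, participant_id = pid, trial_id = trial_id, .before = 1
      )
      troughs_p[[trial_id]] <- truth$troughs
    }
    for (tr in seq_len(config$n_stationary_trials)) {
      set.seed(derive_seed(config$rng_seed, i, config$n_walking_trials + tr))
      dt <- 1 / config$frame_rate
      t <- seq(0, config$trial_duration - dt / 2, by = dt)
      trial_id <- sprintf("s%03d", tr)
      frames[[length(frames) + 1]] <- tibble::tibble(
        participant_id = pid, trial_id = trial_id, condition = "stand",
        t = t, head_x = 0,
        head_y = stats::rnorm(length(t), 0, spec$head_noise_sd),
        head_z = 1.6 + stats::rnorm(length(t), 0, spec$head_noise_sd)
      )
    }
    truth_troughs[[pid]] <- troughs_p
  }

  frames <- dplyr::bind_rows(frames)
  targets <- dplyr::bind_rows(targets)
  targets <- dplyr::select(targets, "participant_id", "trial_id",
                           onset_s = "onset_s", "intensity",
                           "quantile_level", "outcome", "rt_s")
  responses <- dplyr::bind_rows(responses)

  paths <- list(
    frames = file.path(dir, "frames.csv"),
    targets = file.path(dir, "targets.csv"),
    responses = file.path(dir, "responses.csv"),
    manifest = file.path(dir, "manifest.json"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_csv(frames, paths$frames)
  readr::write_csv(targets, paths$targets)
  readr::write_csv(responses, paths$responses)
  jsonlite::write_json(
    list(config = unclass(config), seed = config$rng_seed),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(
    list(participants = purrr::map(specs, unclass),
         troughs = truth_troughs),
    paths$ground_truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' Read a cohort's ground-truth parameter file
#'
#' @param path path to `ground_truth.json` written by [generate_cohort()].
#' @return list with `participants` (list of [participant_spec()]) and
#'   `troughs` (per participant, per trial footfall times).
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- purrr::map(seq_len(nrow(gt$participants)), function(i) {
    row <- as.list(gt$participants[i, ])
    do.call(participant_spec, row)
  })
  list(participants = specs, troughs = gt$troughs)
}
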