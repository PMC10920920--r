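#' Participant specification for the synthetic walker
#'
#' Bundles the ground-truth parameters of one simulated walker-observer:
#' gait (stride duration and vertical head-motion amplitude), the injected
#' stride-phase oscillation of detection performance (frequency in cycles
#' per stride, amplitude on the accuracy and reaction-time scales, phase),
#' baseline performance, and the psychometric observer used by the
#' staircase simulator.
#'
#' @param participant_id character id.
#' @param stride_duration_mean mean stride duration in seconds (two steps).
#' @param stride_duration_sd SD of stride duration across strides, seconds;
#'   per-step jitter is `stride_duration_sd / sqrt(2)`.
#' @param head_amplitude metres, half the peak-to-trough vertical head
#'   excursion per step.
#' @param head_noise_sd metres, additive Gaussian measurement noise.
#' @param osc_frequency injected oscillation frequency, cycles per stride,
#'   in (0, 10].
#' @param osc_amplitude_acc oscillation amplitude on hit probability.
#' @param osc_amplitude_rt oscillation amplitude on reaction time, seconds.
#' @param osc_phase oscillation phase, radians.
#' @param base_hit_rate baseline hit probability.
#' @param base_rt baseline reaction time, seconds.
#' @param rt_noise_sd reaction-time noise SD, seconds.
#' @param observer_threshold,observer_width cumulative-normal observer
#'   parameters on the 0-1 grayscale intensity axis (used by the staircase
#'   simulator only).
#' @return an object of class `participant_spec` (a named list).
#' @export
participant_spec <- function(participant_id = "p01",
                             stride_duration_mean = 1.18,
                             stride_duration_sd = 0.069,
                             head_amplitude = 0.025,
                             head_noise_sd = 0.002,
                             osc_frequency = 2,
                             osc_amplitude_acc = 0.12,
                             osc_amplitude_rt = 0.05,
                             osc_phase = 0,
                             base_hit_rate = 0.75,
                             base_rt = 0.45,
                             rt_noise_sd = 0.08,
                             observer_threshold = 0.44,
                             observer_width = 0.02) {
  spec <- list(
    participant_id = as.character(participant_id),
    stride_duration_mean = stride_duration_mean,
    stride_duration_sd = stride_duration_sd,
    head_amplitude = head_amplitude,
    head_noise_sd = head_noise_sd,
    osc_frequency = osc_frequency,
    osc_amplitude_acc = osc_amplitude_acc,
    osc_amplitude_rt = osc_amplitude_rt,
    osc_phase = osc_phase,
    base_hit_rate = base_hit_rate,
    base_rt = base_rt,
    rt_noise_sd = rt_noise_sd,
    observer_threshold = observer_threshold,
    observer_width = observer_width
  )
  class(spec) <- "participant_spec"
  validate_participant_spec(spec)
  spec
}

validate_participant_spec <- function(spec) {
  probs <- character()
  if (spec$stride_duration_mean <= 0)
    probs <- c(probs, "stride_duration_mean must be > 0")
  if (spec$stride_duration_sd < 0)
    probs <- c(probs, "stride_duration_sd must be >= 0")
  if (spec$osc_frequency <= 0 || spec$osc_frequency > 10)
    probs <- c(probs, "osc_frequency must lie in (0, 10]")
  if (spec$base_hit_rate - spec$osc_amplitude_acc < 0 ||
      spec$base_hit_rate + spec$osc_amplitude_acc > 1)
    probs <- c(probs, "base_hit_rate +/- osc_amplitude_acc must stay in [0, 1]")
  if (spec$base_rt - spec$osc_amplitude_rt <= 0)
    probs <- c(probs, "base_rt - osc_amplitude_rt must be > 0")
  if (length(probs)) {
    stop("invalid participant_spec: ", paste(probs, collapse = "; "),
         call. = FALSE)
  }
  invisible(spec)
}

#' Session configuration for the synthetic walker
#'
#' Trial structure of a simulated session: trial duration and frame rate,
#' walking speed, and the target-scheduling design (anchor times, onset
#' jitter, withholding probability, minimum inter-target interval).
#'
#' Anchors must be at least `min_iti` apart; after jittering, the minimum
#' interval is enforced by pushing any onset that lands too close to its
#' predecessor forward to `predecessor + min_iti` (see
#' [schedule_targets()]).
#'
#' @param n_participants,n_walking_trials,n_stationary_trials counts.
#' @param trial_duration seconds.
#' @param frame_rate Hz of the head/gaze trace.
#' @param walking_speed metres per second.
#' @param target_anchors anchor onset times in seconds; at most 8.
#' @param target_jitter half-width of the uniform onset jitter, seconds.
#' @param withhold_probability probability each target is withheld.
#' @param min_iti minimum inter-target interval, seconds.
#' @param target_duration target presentation duration, seconds.
#' @param rng_seed integer master seed.
#' @return an object of class `session_config`.
#' @export
session_config <- function(n_participants = 36,
                           n_walking_trials = 140,
                           n_stationary_trials = 80,
                           trial_duration = 9,
                           frame_rate = 90,
                           walking_speed = 1.1,
                           target_anchors = seq(0.7, 8.4, length.out = 8),
                           target_jitter = 0.5,
                           withhold_probability = 0.1,
                           min_iti = 0.8,
                           target_duration = 0.02,
                           rng_seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_walking_trials = as.integer(n_walking_trials),
    n_stationary_trials = as.integer(n_stationary_trials),
    trial_duration = trial_duration,
    frame_rate = frame_rate,
    walking_speed = walking_speed,
    target_anchors = sort(target_anchors),
    target_jitter = target_jitter,
    withhold_probability = withhold_probability,
    min_iti = min_iti,
    target_duration = target_duration,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "session_config"
  validate_session_config(cfg)
  cfg
}

validate_session_config <- function(cfg) {
  probs <- character()
  a <- cfg$target_anchors
  if (length(a) > 8) probs <- c(probs, "at most 8 target anchors are allowed")
  if (length(a) >= 2 && min(diff(a)) < cfg$min_iti)
    probs <- c(probs, "consecutive anchors must be >= min_iti apart")
  if (length(a) && (min(a) - cfg$target_jitter <= 0 ||
                    max(a) + cfg$target_jitter >=
                    cfg$trial_duration - cfg$target_duration))
    probs <- c(probs, "jittered onsets can escape (0, trial_duration - target_duration)")
  if (cfg$trial_duration * cfg$frame_rate < 2)
    probs <- c(probs, "trial must contain at least 2 frames")
  if (cfg$withhold_probability < 0 || cfg$withhold_probability > 1)
    probs <- c(probs, "withhold_probability must lie in [0, 1]")
  if (length(probs)) {
    stop("invalid session_config: ", paste(probs, collapse = "; "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Draw a cohort of participant specifications
#'
#' Samples per-participant ground-truth parameters around the cohort-level
#' defaults: stride duration Normal(1.18, 0.069) s across participants,
#' and, for the `n_modulated` first participants, an injected performance
#' oscillation at `osc_frequency` cps; the rest get amplitude 0.
#'
#' @param n number of participants.
#' @param seed integer seed.
#' @param n_modulated how many participants carry a true oscillation.
#' @param osc_frequency cycles per stride of the injected oscillation
#'   (scalar or length-`n_modulated` vector).
#' @param osc_amplitude_acc accuracy-modulation amplitude for modulated
#'   participants.
#' @param osc_phase common injected phase (radians), or `NULL` to draw
#'   phases from a von Mises-like wrapped normal around 0.
#' @return a list of [participant_spec()] objects.
#' @export
sample_participant_specs <- function(n = 36, seed = 1L, n_modulated = n,
                                     osc_frequency = 2,
                                     osc_amplitude_acc = 0.12,
                                     osc_phase = 0) {
  set.seed(seed)
  stride_mu <- stats::rnorm(n, 1.18, 0.069)
  stride_mu <- pmax(stride_mu, 0.8)
  freq <- rep_len(osc_frequency, n_modulated)
  purrr::map(seq_len(n), function(i) {
    modulated <- i <= n_modulated
    participant_spec(
      participant_id = sprintf("p%02d", i),
      stride_duration_mean = stride_mu[i],
      stride_duration_sd = 0.069 / sqrt(2),
      osc_frequency = if (modulated) freq[i] else 2,
      osc_amplitude_acc = if (modulated) osc_amplitude_acc else 0,
      osc_amplitude_rt = if (modulated) 0.05 else 0,
      osc_phase = if (is.null(osc_phase)) wrap_angle(stats::rnorm(1, 0, 0.5))
                  else osc_phase
    )
  })
}
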