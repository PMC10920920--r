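#' QUEST staircase configuration
#'
#' Parameters of the Bayesian adaptive staircase: a discrete intensity
#' grid (grayscale 0.4-1 at 0.004 resolution), a Gaussian prior over the
#' threshold in internal dB units (`dB(c) = 20*log10(c)`), a Weibull
#' trial likelihood with slope `beta`, guess rate and lapse rate, and
#' the seven posterior percentiles from which each trial's contrast is
#' drawn. `p_threshold` anchors the threshold parameter at the intensity
#' yielding that probability of a hit (the classic QUEST convention),
#' which is what makes the staircase hold accuracy near 75%.
#'
#' @param initial_intensity prior mode, grayscale.
#' @param prior_sd prior SD in dB.
#' @param beta Weibull slope.
#' @param lapse,guess lapse and guess rates.
#' @param grain intensity grid step.
#' @param range_low,range_high intensity grid limits.
#' @param quantile_percentiles the seven level percentiles.
#' @param p_threshold hit probability defining the threshold (0.75).
#' @return a `quest_config` list.
#' @export
quest_config <- function(initial_intensity = 0.45, prior_sd = 2,
                         beta = 3.5, lapse = 0.01, guess = 0.5,
                         grain = 0.004, range_low = 0.4, range_high = 1,
                         quantile_percentiles = c(25, 32.25, 37.5, 50,
                                                  62.5, 68.75, 75),
                         p_threshold = 0.75) {
  stopifnot(
    range_low < initial_intensity, initial_intensity < range_high,
    grain > 0,
    !is.unsorted(quantile_percentiles, strictly = TRUE),
    all(quantile_percentiles > 0), all(quantile_percentiles < 100),
    p_threshold > guess, p_threshold < 1 - lapse
  )
  cfg <- list(
    initial_intensity = initial_intensity, prior_sd = prior_sd,
    beta = beta, lapse = lapse, guess = guess, grain = grain,
    range_low = range_low, range_high = range_high,
    quantile_percentiles = quantile_percentiles,
    p_threshold = p_threshold
  )
  class(cfg) <- "quest_config"
  cfg
}

# dB offset that places p_threshold at zero threshold offset
quest_epsilon <- function(cfg) {
  frac <- (cfg$p_threshold - cfg$guess) / (1 - cfg$guess - cfg$lapse)
  20 / cfg$beta * log10(-log1p(-frac))
}

# Weibull hit probability at dB offset d = dB(test) - dB(threshold)
quest_psi <- function(d, cfg) {
  cfg$guess + (1 - cfg$guess - cfg$lapse) *
    (1 - exp(-10^(cfg$beta * (d + quest_epsilon(cfg)) / 20)))
}

#' Initialise a QUEST staircase
#'
#' Builds the threshold grid over `[range_low, range_high]` at `grain`
#' resolution and a Gaussian prior over the threshold, centred at the
#' initial intensity with SD `prior_sd`, both in dB units.
#'
#' @param config a [quest_config()].
#' @return a `quest_state`: list with `config`, `intensity` (grid),
#'   `db` (grid in dB), `posterior` (normalised), `n_trials`.
#' @export
quest_init <- function(config = quest_config()) {
  stopifnot(inherits(config, "quest_config"))
  intensity <- seq(config$range_low, config$range_high, by = config$grain)
  db <- 20 * log10(intensity)
  prior <- stats::dnorm(db, 20 * log10(config$initial_intensity),
                        config$prior_sd)
  state <- list(
    config = config,
    intensity = intensity,
    db = db,
    posterior = prior / sum(prior),
    n_trials = 0L
  )
  class(state) <- "quest_state"
  state
}

#' Bayesian update of the QUEST posterior after one trial
#'
#' Multiplies the posterior over the threshold grid by the Weibull
#' likelihood of the observed outcome at the tested intensity and
#' renormalises. The final posterior is order-invariant in the trial
#' sequence (a product of likelihoods).
#'
#' @param state a `quest_state`.
#' @param tested_intensity the grayscale intensity shown.
#' @param outcome `"hit"`/`"miss"` or 1/0.
#' @return the updated `quest_state`.
#' @export
quest_update <- function(state, tested_intensity, outcome) {
  stopifnot(inherits(state, "quest_state"))
  hit <- if (is.character(outcome)) outcome == "hit" else outcome > 0
  p <- quest_psi(20 * log10(tested_intensity) - state$db, state$config)
  lik <- if (hit) p else 1 - p
  post <- state$posterior * lik
  s <- sum(post)
  if (s <= 0 || !is.finite(s)) {
    stop("QUEST posterior collapsed to zero mass", call. = FALSE)
  }
  state$posterior <- post / s
  state$n_trials <- state$n_trials + 1L
  state
}

#' Posterior quantile intensities (the seven contrast levels)
#'
#' Inverse CDF of the threshold posterior at the configured percentiles,
#' snapped to the intensity grid; monotone non-decreasing across levels
#' Q-3 to Q+3.
#'
#' @param state a `quest_state`.
#' @param percentiles percentiles in (0, 100); defaults to the config's.
#' @return named numeric vector of intensities (`Q-3` ... `Q+3` for the
#'   canonical seven).
#' @export
quest_quantiles <- function(state, percentiles = NULL) {
  if (is.null(percentiles)) percentiles <- state$config$quantile_percentiles
  cdf <- cumsum(state$posterior)
  idx <- vapply(percentiles / 100,
                function(q) which(cdf >= q - 1e-12)[1], integer(1))
  out <- state$intensity[idx]
  if (length(out) == 7) {
    names(out) <- c("Q-3", "Q-2", "Q-1", "Q0", "Q+1", "Q+2", "Q+3")
  }
  out
}

#' Posterior mean threshold intensity
#'
#' @param state a `quest_state`.
#' @return grayscale intensity.
#' @export
quest_mean <- function(state) {
  sum(state$posterior * state$intensity)
}

#' Run a QUEST staircase against an observer
#'
#' The first `n_familiarization` targets are shown at the fixed initial
#' intensity and excluded from fitting (they do not update the
#' staircase). Every subsequent target draws its contrast uniformly
#' from the seven posterior-quantile levels, queries the observer, and
#' updates the posterior.
#'
#' @param observer function of intensity returning 1 (hit) or 0 (miss);
#'   e.g. built from [simulate_staircase_observer()].
#' @param config a [quest_config()].
#' @param n_targets number of targets to run.
#' @param seed integer seed for level draws (observer randomness uses
#'   the same stream).
#' @param n_familiarization fixed-intensity lead-in targets.
#' @return list with `log` (tibble: `trial`, `intensity`,
#'   `level_index` in -3..3, `outcome`, `familiarization`) and `state`
#'   (final `quest_state`).
#' @export
run_staircase <- function(observer, config = quest_config(),
                          n_targets = 500, seed = 1L,
                          n_familiarization = 3) {
  stopifnot(is.function(observer), n_targets >= 1)
  set.seed(seed)
  state <- quest_init(config)
  n_lev <- length(config$quantile_percentiles)
  trial <- seq_len(n_targets)
  intensity <- numeric(n_targets)
  level_index <- integer(n_targets)
  outcome <- integer(n_targets)
  famil <- trial <= n_familiarization
  for (i in trial) {
    if (famil[i]) {
      intensity[i] <- config$initial_intensity
      level_index[i] <- NA_integer_
      outcome[i] <- observer(intensity[i])
      next
    }
    q <- quest_quantiles(state)
    li <- sample.int(n_lev, 1)
    intensity[i] <- q[li]
    level_index[i] <- li - (n_lev + 1) %/% 2
    outcome[i] <- observer(intensity[i])
    state <- quest_update(state, intensity[i], outcome[i])
  }
  list(
    log = tibble::tibble(trial = trial, intensity = intensity,
                         level_index = level_index, outcome = outcome,
                         familiarization = famil),
    state = state
  )
}
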