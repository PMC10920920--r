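test_that("noise-free fixed-step trace has exactly spaced troughs", {
  tr <- clean_trace(step_s = 0.59, trial_s = 9)
  troughs <- attr(tr, "truth")$troughs
  expect_length(troughs, 15)
  expect_equal(unique(round(diff(troughs), 9)), 0.59)
})

test_that("detected stride durations emulate the cohort-level gait stats", {
  spec <- participant_spec(stride_duration_mean = 1.18,
                           stride_duration_sd = 0.069 / sqrt(2))
  cfg <- session_config()
  durs <- unlist(lapply(1:140, function(i) {
    tr <- simulate_head_trace(spec, cfg, seed = i)
    trd <- detrend_height(tr)
    idx <- detect_troughs(trd)
    st <- epoch_strides(idx, trd)
    st$duration_s
  }))
  expect_lt(abs(mean(durs) - 1.18), 0.02)
})

test_that("recorded per-sample phase matches a brute-force recomputation", {
  spec <- participant_spec()
  cfg <- session_config()
  tr <- simulate_head_trace(spec, cfg, seed = 42)
  b <- attr(tr, "truth")$boundaries
  oracle <- vapply(tr$t, function(ti) {
    j <- max(which(b <= ti))
    if (j %% 2 == 0) j <- j - 1  # strides tile from the first boundary
    if (j + 2 > length(b)) return(NA_real_)
    100 * (ti - b[j]) / (b[j + 2] - b[j])
  }, numeric(1))
  expect_equal(tr$true_phase_pct, oracle, tolerance = 1e-12)
})

test_that("target schedule honours withholding, expectation and the ITI", {
  cfg <- session_config()
  cfg_all_withheld <- session_config(withhold_probability = 1)
  for (s in 1:5) {
    expect_length(schedule_targets(cfg_all_withheld, seed = s), 0)
  }
  counts <- vapply(1:1e5, function(s) {
    length(schedule_targets(cfg, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 7.2), 0.02)
  min_gap <- min(vapply(1:1e4, function(s) {
    on <- schedule_targets(cfg, seed = s)
    if (length(on) < 2) Inf else min(diff(on))
  }, numeric(1)))
  expect_gte(min_gap, 0.8 - 1e-12)
  # all onsets inside the trial
  ons <- unlist(lapply(1:2000, function(s) schedule_targets(cfg, seed = s)))
  expect_true(all(ons > 0 & ons < cfg$trial_duration - cfg$target_duration))
})

test_that("outcome model reproduces its own generating curve", {
  # no modulation: pooled rate inside the binomial 99% CI
  spec0 <- participant_spec(osc_amplitude_acc = 0, osc_amplitude_rt = 0)
  ev0 <- simulate_cohort_events(list(spec0), 1e4, seed = 7)
  ci <- qbinom(c(0.005, 0.995), 1e4, spec0$base_hit_rate) / 1e4
  expect_gte(mean(ev0$hit), ci[1])
  expect_lte(mean(ev0$hit), ci[2])

  # modulated: binned curve within per-bin binomial 95% CIs for >= 36/40
  spec <- participant_spec(osc_frequency = 2, osc_amplitude_acc = 0.1,
                           osc_phase = 0.7)
  ev <- simulate_cohort_events(list(spec), 1e4, seed = 8)
  bs <- bin_series(ev, value = hit, n_bins = 40)
  x <- bs$bin_center_pct / 100
  p_true <- spec$base_hit_rate +
    spec$osc_amplitude_acc * cos(2 * pi * 2 * x + 0.7)
  inside <- mapply(function(v, n, p) {
    lo <- qbinom(0.025, n, p) / n
    hi <- qbinom(0.975, n, p) / n
    v >= lo & v <= hi
  }, bs$value, bs$count, p_true)
  expect_gte(sum(inside), 36)
})

test_that("shifting the injected phase by pi shifts the fitted phase by pi", {
  fit_phase <- function(phi0, seed) {
    spec <- participant_spec(osc_frequency = 2, osc_amplitude_acc = 0.15,
                             osc_phase = phi0)
    ev <- simulate_cohort_events(list(spec), 5000, seed = seed)
    fit_fixed_frequency(bin_series(ev, value = hit, n_bins = 40), 2)$phi
  }
  d <- fit_phase(0.4 + pi, 11) - fit_phase(0.4, 11)
  expect_lt(abs(abs(atan2(sin(d), cos(d))) - pi), pi / 8)
})

test_that("staircase observer matches its closed form", {
  spec <- participant_spec(observer_threshold = 0.44,
                           observer_width = 0.02)
  expect_equal(observer_hit_prob(spec$observer_threshold, spec), 0.745)
  spec_steep <- participant_spec(observer_threshold = 0.44,
                                 observer_width = 1e-9)
  expect_equal(observer_hit_prob(1, spec_steep), 0.99)
  expect_error(observer_hit_prob(0.2, spec), "intensity")
  set.seed(3)
  p <- observer_hit_prob(0.45, spec)
  mc <- mean(simulate_staircase_observer(rep(0.45, 1e5), spec))
  expect_lt(abs(mc - p), 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("cohort generation is deterministic and round-trips ground truth", {
  cfg <- session_config(n_participants = 2, n_walking_trials = 2,
                        n_stationary_trials = 1, rng_seed = 5)
  specs <- sample_participant_specs(2, seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, specs, d1)
  generate_cohort(cfg, specs, d2)
  for (f in c("frames.csv", "targets.csv", "responses.csv",
              "manifest.json", "ground_truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  gt <- read_ground_truth(file.path(d1, "ground_truth.json"))
  expect_equal(gt$participants[[1]], specs[[1]], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(gt$participants[[2]]$osc_frequency,
               specs[[2]]$osc_frequency)
})

test_that("targets per participant fall in the emulation band", {
  # per-participant expectation under the stated design is
  # 140 trials x 8 anchors x 0.9 retained = 1008
  cfg <- session_config(n_participants = 1, n_walking_trials = 140)
  n_targets <- sum(vapply(1:140, function(tr) {
    length(schedule_targets(cfg, seed = derive_seed(cfg$rng_seed, 1, tr, 1)))
  }, numeric(1)))
  expect_gte(n_targets, 700)
  expect_lte(n_targets, 1050)
})

test_that("targets fall uniformly over the ground-truth stride cycle", {
  spec <- participant_spec()
  cfg <- session_config()
  ph <- c()
  tr_i <- 1
  while (length(ph) < 1e4) {
    trace <- simulate_head_trace(spec, cfg, seed = tr_i)
    b <- attr(trace, "truth")$boundaries
    on <- schedule_targets(cfg, seed = 10000 + tr_i)
    ph <- c(ph, stats::na.omit(true_stride_phase(on, b)))
    tr_i <- tr_i + 1
  }
  obs <- tabulate(pmin(pmax(ceiling(ph * 20), 1), 20), nbins = 20)
  expect_gt(stats::chisq.test(obs)$p.value, 0.01)
})
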