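make_null_cohort <- function(n_participants, n_events, seed,
                             amplitude = 0) {
  specs <- sample_participant_specs(n_participants, seed = seed,
                                    n_modulated = n_participants,
                                    osc_amplitude_acc = amplitude)
  simulate_cohort_events(specs, n_events, seed = seed)
}

test_that("constant outcomes give an all-zero null distribution", {
  ev <- tibble::tibble(participant_id = "p01",
                       phase_pct = runif(400, 0, 100),
                       hit = rep(1, 400))
  null <- suppressWarnings(
    permutation_null(ev, value = hit, n_perm = 50, seed = 1,
                     level = "participant")
  )
  expect_true(all(null$maxstat == 0))
})

test_that("the critical value is stable across permutation seeds", {
  ev <- make_null_cohort(6, 900, seed = 31)
  c1 <- permutation_null(ev, value = hit, n_perm = 1000, seed = 1)$crit95
  c2 <- permutation_null(ev, value = hit, n_perm = 1000, seed = 2)$crit95
  expect_lt(abs(c1 - c2), 0.05)
})

test_that("significant ranges contain a strong injection and use strict >", {
  specs <- sample_participant_specs(8, seed = 33, n_modulated = 8,
                                    osc_frequency = 2,
                                    osc_amplitude_acc = 0.15)
  ev <- simulate_cohort_events(specs, 900, seed = 33)
  sw <- sweep_frequencies(group_series(ev, value = hit))
  null <- permutation_null(ev, value = hit, n_perm = 200, seed = 5)
  rng <- significant_ranges(sw, null)
  expect_gte(nrow(rng), 1)
  expect_true(any(rng$low_cps <= 2 & rng$high_cps >= 2))

  # boundary rule: r2 exactly equal to crit95 is excluded
  sw_eq <- sw
  sw_eq$r2 <- rep(null$crit95, length(sw$grid))
  expect_equal(nrow(significant_ranges(sw_eq, null)), 0)
})

test_that("participant test recovers the modulated subset of a cohort", {
  n <- 36
  specs <- sample_participant_specs(n, seed = 34, n_modulated = 12,
                                    osc_frequency = 2,
                                    osc_amplitude_acc = 0.15)
  ev <- simulate_cohort_events(specs, 900, seed = 34)
  results <- purrr::map_dfr(sort(unique(ev$participant_id)), function(pid) {
    evp <- dplyr::filter(ev, participant_id == pid)
    ps <- bin_series(evp, value = hit, n_bins = 40)
    sw <- sweep_frequencies(ps)
    null <- permutation_null(evp, value = hit, n_perm = 200,
                             seed = derive_seed(34, match(pid, unique(ev$participant_id))),
                             level = "participant")
    participant_test(sw, null, participant_id = pid, measure = "accuracy")
  })
  k2 <- sum(results$significant & results$band == "two_cps")
  expect_gte(k2, 10)
  expect_lte(k2, 14)
  # unmodulated participants mostly stay null
  unmod <- results$participant_id %in% sprintf("p%02d", 13:36)
  expect_lte(sum(results$significant[unmod]), 4)
})

test_that("a near-perfect oscillation is always significant", {
  x <- ((1:40) - 0.5) / 40
  ev <- tibble::tibble(
    participant_id = "p01",
    phase_pct = rep(100 * x, each = 25),
    hit = rep(as.numeric(cos(2 * pi * 2 * x) > 0), each = 25)
  )
  sw <- sweep_frequencies(bin_series(ev, value = hit, n_bins = 40))
  null <- permutation_null(ev, value = hit, n_perm = 200, seed = 3,
                           level = "participant")
  res <- participant_test(sw, null)
  expect_true(res$significant)
  expect_equal(res$band, "two_cps")
})

test_that("band classification follows the frequency rules", {
  expect_equal(stridecycle:::band_of(2.0, TRUE), "two_cps")
  expect_equal(stridecycle:::band_of(1.5, TRUE), "two_cps")
  expect_equal(stridecycle:::band_of(4.4, TRUE), "four_cps")
  expect_equal(stridecycle:::band_of(6, TRUE), "high")
  expect_equal(stridecycle:::band_of(3.0, TRUE), "none")
  expect_equal(stridecycle:::band_of(2.0, FALSE), "none")
})

test_that("cohort summary counts bands and cross-measure agreement", {
  res <- tibble::tibble(
    participant_id = rep(sprintf("p%02d", 1:4), 2),
    measure = rep(c("accuracy", "rt"), each = 4),
    best_freq = c(2, 4, 6, 3, 2, 4, 2, 3),
    best_r2 = 0.5,
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    band = c("two_cps", "four_cps", "high", "none",
             "two_cps", "four_cps", "two_cps", "none")
  )
  s <- cohort_summary(res)
  acc <- dplyr::filter(s$band_counts, measure == "accuracy")
  expect_equal(acc$k[acc$band == "two_cps"], 1L)
  expect_equal(acc$n, rep(4L, 3))
  # p01, p02 agree across measures; p03 does not (high vs two_cps)
  expect_equal(s$cross_measure_agreement, 2 / 3)

  res_null <- dplyr::mutate(res, significant = FALSE, band = "none")
  s0 <- cohort_summary(res_null)
  expect_true(all(s0$band_counts$k == 0))
})

test_that("stride-duration correlations reflect the cps/Hz construction", {
  set.seed(35)
  dur <- rnorm(36, 1.18, 0.069)
  metrics <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:36),
    stride_duration_s = dur,
    best_freq_cps = rep(2, 36) + rnorm(36, 0, 0.05),
    r2_at_2cps = runif(36, 0.2, 0.8),
    r2_at_4cps = runif(36, 0, 0.3)
  )
  ct <- stride_duration_correlation(metrics)
  hz <- dplyr::filter(ct, metric == "best_freq_hz")
  expect_lt(hz$rho, 0)
  expect_lt(hz$p_value, 0.05)
  cps <- dplyr::filter(ct, metric == "best_freq_cps")
  expect_lt(abs(cps$rho), 0.3)

  expect_error(stride_duration_correlation(metrics[1:4, ]), "at least 5")
  const <- dplyr::mutate(metrics, stride_duration_s = 1.18)
  expect_warning(out <- stride_duration_correlation(const), "constant")
  expect_true(all(is.na(out$rho)))
})
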