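test_that("phase assignment places events at the correct percentile", {
  st <- tiled_strides(stride_s = 1.2, n_strides = 3)
  ev <- tibble::tibble(onset_s = c(0.6, 1.2, 1.8, 3.0, 3.7, 0, 10))
  out <- assign_stride_phase(ev, st)
  expect_equal(out$phase_pct[1], 50)           # stride midpoint
  expect_equal(out$phase_pct[2], 100)          # trough instant: ends stride 1
  expect_equal(out$phase_pct[3], 50)
  expect_equal(out$phase_pct[4], 50)
  expect_true(is.na(out$phase_pct[6]))         # at the very first trough
  expect_equal(out$drop_reason[6], "before first stride")
  expect_equal(out$drop_reason[7], "after last stride")
  # conservation: rows preserved, assigned + dropped = total
  expect_equal(nrow(out), nrow(ev))
  expect_equal(sum(!is.na(out$phase_pct)) + sum(!is.na(out$drop_reason)),
               nrow(ev))
})

test_that("overlapping stride tables are tiled before assignment", {
  tr <- clean_trace()
  trd <- detrend_height(tr)
  st <- epoch_strides(detect_troughs(trd), trd)   # overlapping
  set.seed(4)
  ev <- tibble::tibble(onset_s = runif(4000, st$start_s[1] + 1e-6,
                                       max(st$end_s)))
  out <- assign_stride_phase(ev, st)
  ph <- out$phase_pct[!is.na(out$phase_pct)]
  # full (0, 100] coverage, flat histogram
  expect_gt(max(ph), 90)
  obs <- tabulate(pmin(pmax(ceiling(ph / 5), 1), 20), nbins = 20)
  expect_gt(stats::chisq.test(obs)$p.value, 0.01)
})

test_that("binning reproduces constants, generating curves and densities", {
  ev <- tibble::tibble(phase_pct = seq(0.5, 99.5, by = 0.5),
                       v = rep(0.4, 199))
  bs <- suppressWarnings(bin_series(ev, value = v, n_bins = 40))
  expect_true(all(bs$value == 0.4))
  expect_equal(sum(bs$count), 199)

  # analytic cosine oracle at n = 1e5
  spec <- participant_spec(osc_frequency = 2, osc_amplitude_acc = 0.1,
                           osc_phase = 0)
  ev2 <- simulate_cohort_events(list(spec), 1e5, seed = 12)
  bs2 <- bin_series(ev2, value = hit, n_bins = 40)
  p_true <- spec$base_hit_rate +
    0.1 * cos(2 * pi * 2 * bs2$bin_center_pct / 100)
  inside <- mapply(function(v, n, p) {
    v >= qbinom(0.025, n, p) / n & v <= qbinom(0.975, n, p) / n
  }, bs2$value, bs2$count, p_true)
  # inside ~ Binomial(40, ~0.95): 35 is the ~1% lower tail
  expect_gte(sum(inside), 35)

  # exact uniform density: 400 events, one per quarter percent
  ev3 <- tibble::tibble(phase_pct = seq(0.25, 100, by = 0.25))
  d <- bin_series(ev3, n_bins = 40, statistic = "density")
  expect_true(all(d$value == 1))
})

test_that("empty bins are flagged missing and excluded from the fit", {
  ev <- tibble::tibble(phase_pct = runif(200, 0, 50), v = rnorm(200))
  bs <- suppressWarnings(bin_series(ev, value = v, n_bins = 40))
  expect_true(all(is.na(bs$value[bs$bin_center_pct > 50])))
  fit <- fit_fixed_frequency(bs, 2)
  expect_equal(fit$n_bins_used, sum(!is.na(bs$value)))
})

test_that("response likelihood is flat without modulation and shifts with RT", {
  st <- tiled_strides(stride_s = 1.2, n_strides = 7)
  set.seed(5)
  # null case: uniform targets, constant RT, no modulation
  targ <- tibble::tibble(onset_s = runif(6000, 0.01, 8.3))
  resp <- tibble::tibble(press_onset_s = targ$onset_s + 0.45)
  d <- response_likelihood_series(resp, st, n_bins = 20)
  expect_lt(diff(range(d$value, na.rm = TRUE)), 0.35)  # sampling noise only

  # hits modulated at 2 cps, constant RT: response peak = accuracy peak
  # shifted by RT as a fraction of the stride
  spec <- participant_spec(osc_frequency = 2, osc_amplitude_acc = 0.2,
                           osc_amplitude_rt = 0, rt_noise_sd = 0,
                           osc_phase = 0, base_rt = 0.3)
  stride_s <- 1.2
  x <- runif(3e4)
  hit <- rbinom(3e4, 1, 0.5 + 0.2 * cos(2 * pi * 2 * x))
  press_phase <- (x[hit == 1] + 0.3 / stride_s) %% 1
  resp2 <- tibble::tibble(phase_pct = 100 * press_phase)
  d2 <- bin_series(resp2, n_bins = 40, statistic = "density")
  fit <- fit_fixed_frequency(d2, 2)
  # generating accuracy peak at phase 0; expected response-density peak
  # shifted by 0.3 / 1.2 strides = 0.25, i.e. phi = -2*pi*2*0.25
  expected_phi <- -2 * pi * 2 * (0.3 / stride_s)
  expect_lt(abs(atan2(sin(fit$phi - expected_phi),
                      cos(fit$phi - expected_phi))), pi / 6)

  # zero responses: all-missing series
  d3 <- response_likelihood_series(
    tibble::tibble(press_onset_s = numeric()), st, n_bins = 20)
  expect_true(all(is.na(d3$value)))
})

test_that("clock-time folding behaves at its fixed points", {
  ev <- tibble::tibble(onset_s = 0.25 + 0:7, v = 1)
  cs <- suppressWarnings(
    clocktime_series(ev, value = v, epoch_length_s = 1, n_bins = 20)
  )
  expect_equal(sum(cs$count > 0), 1)
  expect_equal(cs$count[cs$bin_center_pct == 22.5], 8L)

  # epoch length equal to a fixed stride duration with zero jitter:
  # clock-locked and stride-locked fits agree
  spec <- participant_spec(stride_duration_sd = 0, osc_frequency = 2,
                           osc_amplitude_acc = 0.15, osc_phase = 0.5)
  st <- tiled_strides(stride_s = 1.18, n_strides = 7)
  set.seed(6)
  onset <- runif(2e4, 1e-6, 7 * 1.18)
  x <- (onset %% 1.18) / 1.18
  hit <- rbinom(2e4, 1, 0.75 + 0.15 * cos(2 * pi * 2 * x + 0.5))
  ev2 <- tibble::tibble(onset_s = onset, hit = hit)
  stride_fit <- fit_fixed_frequency(
    bin_series(assign_stride_phase(ev2, st), value = hit, n_bins = 40), 2)
  clock_fit <- fit_fixed_frequency(
    clocktime_series(ev2, value = hit, epoch_length_s = 1.18,
                     n_bins = 40), 2)
  expect_equal(clock_fit$A, stride_fit$A, tolerance = 0.25)
  expect_equal(clock_fit$r2, stride_fit$r2, tolerance = 0.25)
})

test_that("stride-locked beats clock-locked when stride durations vary", {
  wins <- 0
  for (c in 1:50) {
    set.seed(100 + c)
    durs <- pmax(rnorm(8, 1.18, 0.069), 0.9)
    stride_max <- clock_max <- -Inf
    ev_all <- list()
    for (p in 1:8) {
      onset <- runif(350, 0, 8 * durs[p])
      x <- (onset %% durs[p]) / durs[p]
      hit <- rbinom(350, 1, 0.75 + 0.12 * cos(2 * pi * 2 * x))
      ev_all[[p]] <- tibble::tibble(
        participant_id = sprintf("p%02d", p), onset_s = onset,
        phase_pct = ifelse(x == 0, 100, 100 * x), hit = hit)
    }
    ev <- dplyr::bind_rows(ev_all)
    sw_stride <- sweep_frequencies(group_series(ev, value = hit))
    clock_group <- ev |>
      dplyr::group_by(participant_id) |>
      dplyr::group_map(~ suppressWarnings(
        clocktime_series(.x, value = hit, n_bins = 40)))
    cv <- rowMeans(sapply(clock_group, function(b) b$value), na.rm = TRUE)
    sw_clock <- sweep_frequencies(series_from_values(cv))
    if (max(sw_stride$r2, na.rm = TRUE) > max(sw_clock$r2, na.rm = TRUE)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 45)
})

test_that("best frequency is stable across 40 and 100 bins", {
  spec <- participant_spec(osc_frequency = 2, osc_amplitude_acc = 0.2)
  ev <- simulate_cohort_events(list(spec), 8000, seed = 31)
  b40 <- sweep_frequencies(bin_series(ev, value = hit, n_bins = 40))
  b100 <- sweep_frequencies(bin_series(ev, value = hit, n_bins = 100))
  expect_lte(abs(b40$best_freq - b100$best_freq), 0.2 + 1e-9)
})
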