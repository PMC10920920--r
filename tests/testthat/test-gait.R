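test_that("detrending removes exactly the least-squares line", {
  t <- seq(0, 9, by = 1 / 90)
  ramp <- tibble::tibble(t = t, head_z = 0.02 * t + 1.6)
  expect_lt(max(abs(detrend_height(ramp)$head_z)), 1e-12)

  set.seed(2)
  noisy <- tibble::tibble(t = t, head_z = sin(2 * pi * t / 1.2) +
                            0.01 * t + rnorm(length(t), 0, 0.05))
  out <- detrend_height(noisy)$head_z
  expect_lt(abs(mean(out)), 1e-12)
  # independent regression oracle
  oracle <- residuals(lm(head_z ~ t, data = noisy))
  expect_equal(out, unname(oracle), tolerance = 1e-10)

  flat <- tibble::tibble(t = t, head_z = rep(1.6, length(t)))
  expect_equal(detrend_height(flat)$head_z, rep(0, length(t)))
})

test_that("trough detection matches analytic minima of a pure sinusoid", {
  t <- seq(0, 9, by = 1 / 90)
  tr <- tibble::tibble(t = t, head_z = 0.02 * cos(2 * pi * t / 0.59))
  idx <- detect_troughs(tr)
  spacing <- diff(t[idx])
  expect_true(all(abs(spacing - 0.59) <= 1 / 90 + 1e-9))
  # analytic minima at (k + 0.5) * 0.59
  expected <- (seq_along(idx) - 0.5) * 0.59
  expect_true(all(abs(t[idx] - expected) <= 1 / 90 + 1e-9))
})

test_that("flat traces yield no troughs", {
  t <- seq(0, 9, by = 1 / 90)
  expect_length(detect_troughs(tibble::tibble(t = t, head_z = 0 * t)), 0)
})

test_that("detector recovers ground-truth troughs under 10% noise", {
  cfg <- session_config()
  matched <- total <- 0
  for (s in 1:100) {
    spec <- participant_spec(head_noise_sd = 0.1 * 0.025)
    tr <- simulate_head_trace(spec, cfg, seed = s)
    truth <- attr(tr, "truth")$troughs
    trd <- detrend_height(tr)
    idx <- detect_troughs(trd)
    det <- trd$t[idx]
    hit <- vapply(truth, function(tt) any(abs(det - tt) <= 2 / 90),
                  logical(1))
    matched <- matched + sum(hit)
    total <- total + length(truth)
  }
  expect_gte(matched / total, 0.95)
})

test_that("stride enumeration counts and durations are correct", {
  tr <- clean_trace()
  trd <- detrend_height(tr)
  idx <- detect_troughs(trd)
  expect_length(idx, 15)
  expect_equal(nrow(epoch_strides(idx, trd)), 13)
  expect_equal(nrow(epoch_strides(idx, trd, overlapping = FALSE)), 7)
  expect_equal(nrow(epoch_strides(integer(), trd)), 0)
  expect_equal(nrow(epoch_strides(idx[1:2], trd)), 0)

  # stride durations equal the sum of their two step durations:
  # align each detected stride with the true troughs it spans
  spec <- participant_spec()
  tr2 <- simulate_head_trace(spec, session_config(), seed = 10)
  truth <- attr(tr2, "truth")$troughs
  trd2 <- detrend_height(tr2)
  st <- epoch_strides(detect_troughs(trd2), trd2)
  steps <- diff(truth)
  for (i in seq_len(nrow(st))) {
    j <- which.min(abs(truth - st$start_s[i]))
    if (j + 2 > length(truth)) next
    expect_equal(st$duration_s[i], steps[j] + steps[j + 1],
                 tolerance = 3 / 90)
  }
})

test_that("noise-free detected stride durations match truth within a frame", {
  spec <- participant_spec(head_noise_sd = 0)
  cfg <- session_config()
  for (s in 1:10) {
    tr <- simulate_head_trace(spec, cfg, seed = s)
    truth <- attr(tr, "truth")$troughs
    trd <- detrend_height(tr)
    st <- epoch_strides(detect_troughs(trd), trd)
    # compare each detected stride against the true troughs it spans
    for (i in seq_len(nrow(st))) {
      j <- which.min(abs(truth - st$start_s[i]))
      if (j + 2 > length(truth)) next
      # one frame: each endpoint is grid-quantised by up to half a
      # frame; 0.1 ms slack covers the detrending tilt
      expect_lte(abs(st$duration_s[i] - (truth[j + 2] - truth[j])),
                 1 / 90 + 1e-4)
    }
  }
})

test_that("stride resampling reproduces analytic curves on the phase grid", {
  t <- seq(0, 3, by = 1 / 90)
  ramp <- tibble::tibble(t = t, head_z = 2 * t + 1)
  rs <- resample_stride(0.5, 1.7, ramp)
  expect_length(rs, 200)
  grid <- 0.5 + (1:200) / 200 * 1.2
  expect_equal(rs, 2 * grid + 1, tolerance = 1e-12)

  dur <- 1.18
  sine <- tibble::tibble(t = t, head_z = 0.02 * sin(2 * pi * t / dur))
  rs2 <- resample_stride(0.3, 0.3 + dur, sine)
  grid2 <- 0.3 + (1:200) / 200 * dur
  expect_lt(max(abs(rs2 - 0.02 * sin(2 * pi * grid2 / dur))), 1e-3 * 0.02)

  expect_null(resample_stride(0.5, 0.52, ramp))
})

test_that("resampling an already-resampled stride is idempotent", {
  tr <- clean_trace()
  trd <- detrend_height(tr)
  st <- epoch_strides(detect_troughs(trd), trd)
  r1 <- resample_stride(st$start_s[2], st$end_s[2], trd)
  grid_t <- st$start_s[2] + (1:200) / 200 * (st$end_s[2] - st$start_s[2])
  refed <- tibble::tibble(t = grid_t, head_z = r1)
  r2 <- resample_stride(st$start_s[2], st$end_s[2], refed)
  expect_equal(r2, r1, tolerance = 1e-9)
})

test_that("trial QC rejects drop-outs, flat and implausible traces", {
  tr <- clean_trace()
  trd <- detrend_height(tr)
  idx <- detect_troughs(trd)
  expect_true(qc_trials(trd, idx)$accept)

  gap <- trd[trd$t < 4 | trd$t > 4.5, ]
  qc <- qc_trials(gap, detect_troughs(gap))
  expect_false(qc$accept)
  expect_equal(qc$reason, "drop-out")

  flat <- tibble::tibble(t = trd$t, head_z = rep(0, nrow(trd)))
  expect_equal(qc_trials(flat, integer())$reason, "flat signal")

  # too-slow oscillation: troughs spaced 1.5 s
  t <- seq(0, 9, by = 1 / 90)
  slow <- tibble::tibble(t = t, head_z = 0.02 * cos(2 * pi * t / 1.5))
  qs <- qc_trials(slow, detect_troughs(slow))
  expect_false(qs$accept)
  expect_equal(qs$reason, "implausible step duration")

  nan <- trd
  nan$head_z[100] <- NaN
  expect_equal(qc_trials(nan, idx)$reason, "drop-out")
})

test_that("extract_gait rejects exactly the corrupted trials in a cohort", {
  spec <- participant_spec()
  cfg <- session_config()
  frames <- purrr::map_dfr(1:40, function(tr_i) {
    tr <- simulate_head_trace(spec, cfg, seed = tr_i)
    tr$participant_id <- "p01"
    tr$trial_id <- sprintf("w%03d", tr_i)
    # corrupt a known 10%: flatten the signal mid-trial (signal loss)
    if (tr_i %% 10 == 0) tr$head_z[200:500] <- NA
    tr[, c("participant_id", "trial_id", "t", "head_z")]
  })
  res <- extract_gait(frames)
  expect_equal(sum(!res$qc$accept), 4)
  expect_setequal(res$qc$trial_id[!res$qc$accept],
                  sprintf("w%03d", c(10, 20, 30, 40)))
  expect_false(any(res$strides$trial_id %in%
                     res$qc$trial_id[!res$qc$accept]))
})
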