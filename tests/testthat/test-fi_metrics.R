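make_step_curve <- function(step_time = 12, level = 100, base = 10,
                            fr = 25, dur = 40, injection = 10) {
  times <- (0:(dur * fr - 1)) / fr
  y <- ifelse(times < step_time, base, level)
  time_intensity_curve(times, y, injection)
}

test_that("baseline statistics match hand computation", {
  times <- (0:249) / 25
  cv <- time_intensity_curve(times, rep(10, 250), injection_time = 5)
  b <- baseline_statistics(cv, 5)
  expect_equal(b$mean, 10)
  expect_equal(b$sd, 0)
  expect_false(b$short_baseline)

  y <- rep(c(8, 10, 12), length.out = 250)
  cv2 <- time_intensity_curve(times, y, injection_time = 0.12)
  b2 <- baseline_statistics(cv2, 0.12)  # frames at t = 0, 0.04, 0.08: {8,10,12}
  expect_equal(b2$mean, 10)
  expect_equal(b2$sd, sd(c(8, 10, 12)))  # sample (n-1) estimator
  expect_true(b2$short_baseline)         # fewer than 5 frames

  cv3 <- time_intensity_curve(times, y, injection_time = 0)
  expect_error(baseline_statistics(cv3, 5), class = "pq_unusable_curve")
})

test_that("moving-average smoothing: identity, constants, ramps", {
  cv <- make_random_curve(5)$curve
  expect_identical(smooth_curve(cv, 0), cv)
  const <- time_intensity_curve((0:99) / 25, rep(7, 100), 1)
  expect_equal(smooth_curve(const, 3)$intensities, rep(7, 100))
  ramp <- time_intensity_curve((0:99) / 25, seq(0, 99), 1)
  sm <- smooth_curve(ramp, 2)
  expect_equal(sm$intensities[3:98], ramp$intensities[3:98])  # interior exact
})

test_that("onset detection: clean step, flat curve, backtracking", {
  cv <- make_step_curve(step_time = 12)
  b <- baseline_statistics(cv, 5)
  on <- detect_onset(cv, b, k = 3, m = 3)
  expect_false(on$no_onset)
  expect_equal(on$onset_time, 12.0)
  expect_equal(on$onset_time - cv$injection_time, 2.0)

  flat <- time_intensity_curve((0:999) / 25, rep(10, 1000), 10)
  bf <- baseline_statistics(flat, 5)
  expect_true(detect_onset(flat, bf)$no_onset)

  # backtracking walks from the threshold crossing down to the baseline
  clean <- make_clean_curve()
  bc <- baseline_statistics(clean, 5)
  with_bt <- detect_onset(clean, bc, backtrack = TRUE)
  no_bt <- detect_onset(clean, bc, backtrack = FALSE)
  expect_lt(with_bt$onset_time, no_bt$onset_time)
  expect_equal(with_bt$onset_time, 14.04, tolerance = 1e-9)
})

test_that("BSFI: offset invariance, tie rule, truncation", {
  cv <- make_clean_curve()
  b <- baseline_statistics(cv, 5)
  r1 <- compute_bsfi(cv, b)
  shifted <- cv; shifted$intensities <- cv$intensities + 37
  bs <- baseline_statistics(shifted, 5)
  r2 <- compute_bsfi(shifted, bs)
  expect_equal(r2$bsfi, r1$bsfi, tolerance = 1e-12)

  # two equal maxima at 20 s and 40 s resolve to the earlier
  times <- (0:(60 * 25 - 1)) / 25
  y <- rep(1, length(times)); y[times == 20] <- 9; y[times == 40] <- 9
  tie <- time_intensity_curve(times, y, 10)
  bt <- baseline_statistics(tie, 5)
  expect_equal(compute_bsfi(tie, bt)$peak_time, 20)

  short <- time_intensity_curve((0:(30 * 25 - 1)) / 25,
                                gamma_variate((0:(30 * 25 - 1)) / 25, bolus_params()),
                                10)
  expect_true(compute_bsfi(short, baseline_statistics(short, 5), 60)$window_truncated)
})

test_that("SFI: exact ramp, finite-difference limit, brute-force oracle", {
  times <- (0:(40 * 25 - 1)) / 25
  y <- ifelse(times < 14, 10, 10 + 5 * (times - 14))
  ramp <- time_intensity_curve(times, pmin(y, 10 + 5 * 8), 10)
  expect_equal(compute_sfi(ramp, 14, 22, 13)$sfi, 5.0, tolerance = 1e-12)
  expect_equal(compute_sfi(ramp, 14, 22, 2)$sfi, 5.0, tolerance = 1e-9)

  for (seed in c(2, 13)) {
    rc <- make_random_curve(seed)
    cv <- rc$curve
    onset <- rc$truth$onset_time
    peak <- onset + rc$truth$time_to_peak
    got <- compute_sfi(cv, onset, peak, 13)$sfi
    expect_equal(got, sfi_bruteforce(cv, onset, peak, 13), tolerance = 1e-9)
  }
})

test_that("SFI falls back to the full segment when the rise is short", {
  times <- (0:(40 * 25 - 1)) / 25
  y <- 10 + 3 * pmax(times - 14, 0)
  cv <- time_intensity_curve(times, y, 10)
  r <- compute_sfi(cv, 14, 14.2, 13)   # 6 frames < 13
  expect_true(r$short_rise)
  expect_equal(r$sfi, 3.0, tolerance = 1e-9)
})

test_that("TTS ratio: identity, simple ratio, undefined cases", {
  a <- list(tts = 4); b <- list(tts = 2)
  expect_equal(compute_tts_ratio(a, a)$tts_ratio, 1.0)
  expect_equal(compute_tts_ratio(a, b)$tts_ratio, 2.0)
  expect_true(compute_tts_ratio(list(tts = NA_real_), b)$undefined_ratio)
  expect_true(compute_tts_ratio(a, list(tts = 0))$undefined_ratio)
})

test_that("analyze_curve flags saturation on clipped 8-bit curves", {
  acq <- acquisition_config(noise_sd = 0, seed = 1)
  d <- sim_defaults(); d$amplitude_d3 <- 400  # clips hard at 255
  cv <- simulate_curve(roi_perfusion_spec("D3"), 1, acq, d)
  res <- analyze_curve(cv)
  expect_true("saturated" %in% res$flags)
  res_ok <- analyze_curve(simulate_curve(roi_perfusion_spec("D3"), 1, acq))
  expect_false("saturated" %in% res_ok$flags)
})

test_that("analyze_experiment produces a tidy table with reference ratio 1", {
  ex <- simulate_experiment(acquisition_config(seed = 8))
  an <- analyze_experiment(ex, animal_id = "A9")
  expect_equal(nrow(an$table), 12L)
  expect_setequal(names(an$table),
                  c("animal_id", "roi", "state", "bsfi", "sfi", "tts",
                    "tts_ratio", "onset_time", "peak_time", "flags"))
  expect_true(all(an$table$tts_ratio[an$table$roi == "D3"] == 1))
  expect_true(all(an$table$tts_ratio[an$table$roi == "D1"] >
                  an$table$tts_ratio[an$table$roi == "D2"]))
})
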