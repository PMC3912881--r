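test_that("median filter matches hand-computed medians with replicate padding", {
  rr <- rr_series(cumsum(c(800, 810, 1600, 805, 795)) / 1000,
    c(800, 810, 1600, 805, 795)
  )
  out <- median_filter_rr(rr, 3)
  expect_equal(out$rr_ms, c(800, 810, 810, 805, 795))
  expect_equal(out$t_s, rr_origin(rr) + cumsum(out$rr_ms) / 1000)
})

test_that("median filter leaves constant series unchanged and rejects even kernels", {
  rr <- rr_series(cumsum(rep(0.8, 20)), rep(800, 20))
  expect_equal(median_filter_rr(rr, 5)$rr_ms, rr$rr_ms)
  expect_error(median_filter_rr(rr, 4), "odd")
  expect_error(median_filter_rr(rr[1:3, ], 5), "shorter")
})

test_that("median filter restores injected ectopics", {
  clean <- generate_rr(rr_modulation_spec(
    amp_lf = 20, amp_hf = 10,
    noise_sd = 5, duration = 600, seed = 21
  ))
  dirty <- inject_ectopics(clean, rate = 0.02, magnitude = 0.4, seed = 22)
  idx <- attr(dirty, "corrupted_beats")
  repaired <- median_filter_rr(dirty, 5)
  rel_err <- abs(repaired$rr_ms[idx] - clean$rr_ms[idx]) / clean$rr_ms[idx]
  expect_gte(mean(rel_err <= 0.05), 0.9)
})

test_that("spline resampling is exact on constants and at knot times", {
  rr <- rr_series(cumsum(rep(0.8, 40)), rep(800, 40))
  u <- resample_rr(rr, 4)
  expect_equal(u$value, rep(800, nrow(u)))
  expect_equal(attr(u, "rate"), 4)
  # beats at multiples of 250 ms: the 4 Hz grid hits every knot exactly
  rr_vals <- 250 * rep(c(3, 4, 3, 3, 4), 8)
  mod <- rr_series(cumsum(rr_vals) / 1000, rr_vals)
  um <- resample_rr(mod, 4)
  knot_idx <- match(round(mod$t_s, 9), round(um$t_s, 9))
  expect_equal(um$value[knot_idx], mod$rr_ms)
  expect_error(resample_rr(rr[1:3, ], 4), "at least 4")
})

test_that("resampling preserves the amplitude of a slow modulation", {
  t <- cumsum(rep(0.75, 400))
  mod <- 800 + 30 * sin(2 * pi * 0.1 * t)
  rr2 <- rr_series(cumsum(mod) / 1000, mod)
  u <- resample_rr(rr2, 4)
  interior <- u$t_s > 20 & u$t_s < max(u$t_s) - 20
  amp <- (max(u$value[interior]) - min(u$value[interior])) / 2
  expect_lt(abs(amp - 30) / 30, 0.02)
})

test_that("butterworth bandpass passes the band and rejects out-of-band", {
  pass <- butterworth_filter(sinusoid_series(0.25), 0.04, 0.4)
  core <- pass$t_s > 100 & pass$t_s < 500
  expect_lt(abs(max(abs(pass$value[core])) - 1), 0.05)
  stop <- butterworth_filter(sinusoid_series(0.01), 0.04, 0.4)
  expect_lt(max(abs(stop$value[core])), 10^(-20 / 20)) # >= 20 dB down
  zero <- butterworth_filter(
    uniform_series(seq(0, 100, 0.25), rep(0, 401), 4), 0.04, 0.4
  )
  expect_equal(zero$value, rep(0, 401))
  expect_error(
    butterworth_filter(sinusoid_series(0.1), 0.04, 2.5),
    "Nyquist"
  )
})

test_that("band powers recover analytic sinusoid power in the right band", {
  track <- band_power_track(sinusoid_series(0.095, amp = 30, offset = 800))
  expect_true(all(abs(track$lf_ms2 - 450) / 450 < 0.05))
  expect_true(all(track$hf_ms2 < 0.05 * 450)) # >= 95% in the correct band
  hf_track <- band_power_track(sinusoid_series(0.25, amp = 30, offset = 800))
  expect_true(all(abs(hf_track$hf_ms2 - 450) / 450 < 0.05))
  expect_true(all(hf_track$lf_ms2 < 0.05 * 450))
})

test_that("band power is homogeneous of degree two and ratios scale-free", {
  rr <- generate_rr(rr_modulation_spec(
    amp_lf = 20, amp_hf = 20,
    noise_sd = 0, duration = 400, seed = 31
  ))
  u <- resample_rr(rr, 4)
  scaled <- uniform_series(u$t_s, 800 + 2 * (u$value - 800), 4)
  t1 <- band_power_track(u)
  t2 <- band_power_track(scaled)
  expect_equal(t2$lf_ms2, 4 * t1$lf_ms2, tolerance = 1e-9)
  expect_equal(t2$hf_ms2, 4 * t1$hf_ms2, tolerance = 1e-9)
  expect_equal(t2$ratio, t1$ratio, tolerance = 1e-9)
})

test_that("equal-amplitude modulation gives near-unity windowed ratios", {
  rr <- generate_rr(rr_modulation_spec(
    amp_lf = 30, amp_hf = 30,
    noise_sd = 0, duration = 400, seed = 32
  ))
  track <- rr_to_track(rr)
  expect_true(all(abs(track$ratio - 1) < 0.15))
})

test_that("segment means follow the half-open window-center convention", {
  track <- structure(
    tibble::tibble(
      window_center_s = c(30, 60, 90, 120),
      lf_ms2 = 1, hf_ms2 = 1, ratio = c(1, 3, 2, 2)
    ),
    class = c("band_power_track", class(tibble::tibble()))
  )
  res <- segment_mean_ratio(track, 0, 90, segment = "first")
  expect_equal(res$mean_ratio, 2)
  expect_equal(res$sd_ratio, sqrt(2))
  expect_equal(res$n_windows, 2)
  all_two <- segment_mean_ratio(track, 85, 125)
  expect_equal(all_two$mean_ratio, 2)
  expect_equal(all_two$sd_ratio, 0)
  expect_error(segment_mean_ratio(track, 200, 300, "late"), "late")
})

test_that("r-peak detection recovers constructed and generated beat times", {
  beats <- seq(0.5, 30, by = 0.8)
  ecg <- synthesize_ecg(beats)
  det <- detect_r_peaks(ecg)
  expect_equal(length(det), length(beats))
  expect_true(all(abs(diff(det) - 0.8) <= 1 / 250 + 1e-9))
  # refractory suppression: second of a close pair vanishes
  close <- synthesize_ecg(c(1, 1.1, 2, 3))
  expect_equal(length(detect_r_peaks(close, refractory = 0.25)), 3)
  # flat trace warns and returns nothing
  flat <- synthesize_ecg(5)
  flat$amplitude <- 0 * flat$amplitude
  expect_warning(out <- detect_r_peaks(flat), "flat")
  expect_length(out, 0)
  # round trip against the generator
  rr <- generate_rr(rr_modulation_spec(noise_sd = 10, duration = 60, seed = 41))
  trace <- synthesize_ecg(c(rr_origin(rr), rr$t_s) + 1) # offset into the trace
  det2 <- detect_r_peaks(trace)
  expect_equal(length(det2), nrow(rr) + 1)
  expect_true(all(abs(diff(det2) * 1000 - rr$rr_ms) <= 1000 / 250 + 1e-6))
})
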