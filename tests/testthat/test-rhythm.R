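test_that("background correction is exact for linear drift", {
  # zero signal, linear background drift: corrected mean should be a tiny
  # fraction of the background level (the subtraction shares the closed-
  # minute noise across each 15-min block, so the plain Poisson SE of the
  # mean does not apply; 2% of background is far above the residual noise)
  tr <- generate_bioluminescence(6, days = 3, amplitude = 0,
                                 background = 400, bg_slope = 50,
                                 bg_sin_amp = 0, seed = 1)
  ct <- background_correct(tr)
  expect_lt(abs(mean(ct$corrected)), 0.02 * 400)
  # noiseless check: exact cancellation everywhere, ends included
  tr$counts <- 100 + 2 * tr$minute / 1440
  ct2 <- background_correct(tr)
  expect_lt(max(abs(ct2$corrected)), 1e-9)
  tr$shutter_open <- rep(TRUE, length(tr$shutter_open))
  expect_error(background_correct(tr), "no closed")
})

test_that("corrected signal agrees with and without background", {
  tr_a <- generate_bioluminescence(6, days = 3, amplitude = 300,
                                   background = 500, seed = 2)
  tr_b <- generate_bioluminescence(6, days = 3, amplitude = 300,
                                   background = 500, bg_slope = 0,
                                   bg_sin_amp = 0, seed = 2)
  a <- chronodelay:::block_average_15min(background_correct(tr_a))
  b <- chronodelay:::block_average_15min(background_correct(tr_b))
  expect_gt(cor(a$y, b$y), 0.95)
})

test_that("MODWT decomposition reconstructs and separates bands", {
  set.seed(3)
  x <- rnorm(480)
  mra <- chronodelay:::modwt_mra(x, 6)
  expect_equal(Reduce(`+`, mra$details) + mra$smooth, x, tolerance = 1e-9)
  t_h <- (1:480 - 0.5) * 0.25
  in_band <- dwt_detrend(list(y = cos(2 * pi * t_h / 24), dt_h = 0.25))
  expect_gt(cor(in_band$y, cos(2 * pi * t_h / 24)), 0.99)
  out_band <- dwt_detrend(list(y = cos(2 * pi * t_h / 1), dt_h = 0.25))
  expect_lt(sd(out_band$y) / sd(cos(2 * pi * t_h)), 0.05)
  with_trend <- dwt_detrend(list(y = cos(2 * pi * t_h / 24) + 0.01 * t_h,
                                 dt_h = 0.25))
  leak <- max(abs(with_trend$y - in_band$y)) / (0.01 * diff(range(t_h)))
  expect_lt(leak, 0.05)
  expect_error(dwt_detrend(list(y = rnorm(100), dt_h = 0.25)), "2 days")
})

test_that("acrophase recovers the programmed phase and is shift-equivariant", {
  tr <- generate_bioluminescence(6, tau_true = 24, days = 5, seed = 4)
  est <- acrophase(dwt_detrend(background_correct(tr)))
  expect_gte(est$phi_h, 5.75)
  expect_lte(est$phi_h, 6.25)
  # equivariance: +3 h phase shift of the generator moves the estimate +3 h
  tr3 <- generate_bioluminescence(9, tau_true = 24, days = 5, seed = 4)
  est3 <- acrophase(dwt_detrend(background_correct(tr3)))
  expect_equal(wrap_phase(est3$phi_h - est$phi_h), 3, tolerance = 0.25)
})

test_that("acrophase and period recover over many seeds", {
  phi_err <- vapply(1:10, function(s) {
    tr <- generate_bioluminescence(6, 24, 5, seed = 100 + s)
    acrophase(dwt_detrend(background_correct(tr)))$phi_h - 6
  }, numeric(1))
  expect_true(all(abs(phi_err) < 0.25))
  tau_err <- vapply(1:10, function(s) {
    tr <- generate_bioluminescence(6, 23.7, 5, seed = 200 + s)
    estimate_period(dwt_detrend(background_correct(tr))) - 23.7
  }, numeric(1))
  expect_true(all(abs(tau_err) < 0.15))
})

test_that("period estimation handles 23.5 and 24 h and ignores amplitude", {
  tr <- generate_bioluminescence(6, 23.5, 5, seed = 5)
  expect_equal(estimate_period(dwt_detrend(background_correct(tr))), 23.5,
               tolerance = 0.15)
  tr24 <- generate_bioluminescence(6, 24, 5, seed = 6)
  expect_equal(estimate_period(dwt_detrend(background_correct(tr24))), 24,
               tolerance = 0.15)
  hi <- generate_bioluminescence(6, 23.7, 5, amplitude = 800, seed = 7)
  lo <- generate_bioluminescence(6, 23.7, 5, amplitude = 200, seed = 7)
  t_hi <- estimate_period(dwt_detrend(background_correct(hi)))
  t_lo <- estimate_period(dwt_detrend(background_correct(lo)))
  expect_equal(t_hi, t_lo, tolerance = 0.1)
})

test_that("SNR separates rhythmic from noisy traces and scales with amplitude", {
  rhythmic <- generate_bioluminescence(6, 24, 5, amplitude = 400, seed = 8)
  expect_gt(rhythm_snr(background_correct(rhythmic)), 10)
  flat <- generate_bioluminescence(6, 24, 5, amplitude = 0, seed = 9)
  expect_lt(rhythm_snr(background_correct(flat)), 1.5)
  half <- generate_bioluminescence(6, 24, 5, amplitude = 200, seed = 10)
  ratio <- rhythm_snr(background_correct(rhythmic)) /
    rhythm_snr(background_correct(half))
  expect_equal(ratio, 4, tolerance = 0.9)
})

test_that("wavelet power peaks at the dominant activity period", {
  zt <- ((seq_len(6 * 8640) - 0.5) / 360) %% 24
  square <- as.integer(ifelse(zt >= 12, 3, 0))
  ps <- cwt_power(square)
  expect_equal(ps$period_h[which.max(ps$power)], 24, tolerance = 2)
  expect_true(all(ps$power >= 0, na.rm = TRUE))
})

test_that("ultradian evening activity raises 8-h wavelet power", {
  sch <- make_schedule("DLE", 6)
  tri <- generate_activity(activity_params(psi_target_h = 3.59,
                                           ultradian_depth = 0.8,
                                           seed = 11), sch)
  smooth <- generate_activity(activity_params(psi_target_h = 3.59,
                                              seed = 11), sch)
  p_tri <- attr(cwt_power(tri), "power_8h")
  p_smooth <- attr(cwt_power(smooth), "power_8h")
  expect_gt(p_tri / p_smooth, 1)
})

test_that("white noise has no outstanding wavelet peak", {
  set.seed(12)
  pw <- morlet_power(rnorm(1440), dt_h = 0.1)
  expect_lt(max(pw$power, na.rm = TRUE),
            3 * stats::median(pw$power, na.rm = TRUE))
})
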