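test_that("phase-delay recursion equals its closed form", {
  p <- activity_params(psi_target_h = 3.59, k_reentrain = 0.3)
  protos <- c(rep("LD", 7), rep("DLE", 13))
  psi <- chronodelay:::psi_trajectory(p, protos)
  d <- 1:13
  expect_equal(psi[7 + d, "onset"], 3.59 * (1 - 0.7^d), tolerance = 1e-12)
  expect_true(all(psi[1:7, ] == 0))
  # convergence: within 0.11 h of target by day 10
  expect_lt(abs(psi[17, "onset"] - 3.59), 0.11)
})

test_that("DD days drift by tau - 24 per day from the entrained phase", {
  p <- activity_params(psi_init_h = 4, tau_h = 23.7)
  psi <- chronodelay:::psi_trajectory(p, rep("DD", 5))
  expect_equal(psi[, "onset"], 4 + (1:5) * (23.7 - 24), tolerance = 1e-12)
})

test_that("LD generation is nocturnal with the programmed rate contrast", {
  rec <- generate_activity(activity_params(seed = 3), make_schedule("LD", 3))
  counts <- rec$counts
  zt <- ((seq_along(counts) - 0.5) / 360) %% 24
  night <- mean(counts[zt >= 12.5 & zt < 23.5])
  day <- mean(counts[zt >= 0.5 & zt < 11.5])
  expect_gt(night / day, 5)
  expect_equal(night / day, 2.0 / 0.15, tolerance = 0.25)
  expect_true(all(counts >= 0))
  expect_equal(length(counts), 3 * 8640)
})

test_that("fixed seed gives bit-identical recordings", {
  s <- make_schedule("DLE", 2)
  a <- generate_activity(activity_params(psi_target_h = 2, seed = 11), s)
  b <- generate_activity(activity_params(psi_target_h = 2, seed = 11), s)
  expect_identical(a$counts, b$counts)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("dim-evening counts scale with the masking factor", {
  # steady-state DLE with a delayed onset (~15.6 h): bins in ZT 12.5-14.5
  # are dim-lit rest on late days, so their rate is lambda_rest * masking
  # exactly, independent of the active-window calibration
  s <- c(make_schedule("LD", 7), make_schedule("DLE", 13))
  mean_evening_rest <- function(masking) {
    p <- activity_params(psi_target_h = 3.59, psi_midpoint_h = 2.57,
                         psi_offset_h = 2.52, masking = masking, seed = 21)
    rec <- generate_activity(p, s)
    h <- (seq_along(rec$counts) - 0.5) / 360
    zt <- h %% 24
    late <- h >= 13 * 24
    mean(rec$counts[late & zt >= 12.5 & zt < 14.5])
  }
  m1 <- mean_evening_rest(1.0)
  m08 <- mean_evening_rest(0.8)
  expect_equal(m08 / m1, 0.8, tolerance = 0.15)
})

test_that("parameter validation rejects inconsistent settings", {
  expect_error(activity_params(lambda_active = 0.1, lambda_rest = 0.2))
  expect_error(activity_params(k_reentrain = 0))
  expect_error(activity_params(masking = 1.2))
  expect_error(activity_params(ultradian_depth = 2))
})

test_that("ground-truth markers sit where the noiseless pipeline detects them", {
  # the generator calibrates window edges so that the detectable markers of
  # the noiseless rate coincide with the stored ground truth
  ps <- activity_preset("wt_dle", seed = 1)
  rec <- generate_activity(ps$params, ps$schedule)
  gt <- rec$ground_truth
  d <- 18  # steady state
  lux_day <- lux_at(ps$schedule, (seq_len(8640) - 0.5) / 360 + 24 * (d - 1))
  wc <- chronodelay:::calibrate_window(gt$onset_zt[d], gt$midpoint_zt[d],
                                       gt$offset_zt[d], lux_day, ps$params)
  det <- chronodelay:::detect_noiseless(
    chronodelay:::day_rate(wc["a"], wc["m"], wc["b"], lux_day, ps$params))
  expect_equal(unname(det["onset"]), gt$onset_zt[d], tolerance = 0.02)
  expect_equal(unname(det["midpoint"]), gt$midpoint_zt[d], tolerance = 0.02)
  expect_equal(unname(det["offset"]), gt$offset_zt[d], tolerance = 0.02)
})

test_that("bioluminescence generator respects the shutter contract", {
  tr <- generate_bioluminescence(phi_true = 6, days = 2, seed = 4)
  expect_equal(length(tr$counts), 2 * 1440)
  # exactly one closed minute per 15-minute block
  blocks <- split(tr$shutter_open, rep(seq_len(length(tr$counts) / 15),
                                       each = 15))
  expect_true(all(vapply(blocks, function(b) sum(!b) == 1L, logical(1))))
  expect_true(all(tr$counts >= 0))
  expect_error(generate_bioluminescence(6, days = 1))
  expect_error(generate_bioluminescence(6, days = 3, background = 0))
})

test_that("zero-amplitude bioluminescence corrects to near zero", {
  tr <- generate_bioluminescence(phi_true = 6, days = 3, amplitude = 0,
                                 seed = 5)
  ct <- background_correct(tr)
  expect_lt(abs(mean(ct$corrected)), 0.02 * 300)
})

test_that("qPCR generator encodes the programmed cosine in Ct space", {
  tru <- qpcr_truth(tissues = "liver", gene = "g", phi_ld = 14, phi_dle = 14)
  tab <- generate_qpcr(tru, noise_sd_ct = 0, seed = 6)
  tgt <- tab[tab$role == "target" & tab$condition == "LD", ]
  m <- tapply(tgt$ct, tgt$zt, mean)
  # lowest Ct (highest expression) at ZT14
  expect_equal(as.numeric(names(which.min(m))), 14)
  # both housekeeping genes present in every sample
  hk <- tab[tab$role == "housekeeping", ]
  expect_true(all(table(hk$sample_id) == 2))
  expect_error(generate_qpcr(qpcr_truth(mesor = 1, amplitude = 1.5)))
})

test_that("recognition generator respects the trial plan and bounds", {
  rec <- generate_recognition(n_mice = 3, seed = 8)
  expect_equal(nrow(rec), 3 * 8)
  expect_equal(as.integer(table(rec$condition)), c(12L, 12L))
  r <- recognition_ratio(rec$novel_0_60, rec$familiar_0_60)
  expect_true(all(r >= 0 & r <= 1))
  expect_error(generate_recognition(n_mice = 1))
})
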