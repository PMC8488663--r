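test_that("moving average matches direct means and handles edges", {
  expect_equal(moving_average(rep(3, 10), 3), c(NA, rep(3, 8), NA))
  expect_equal(moving_average(c(0, 0, 6, 0, 0), 3), c(NA, 2, 2, 2, NA))
  # impulse response: plateau of 1/w spanning w bins
  x <- numeric(21); x[11] <- 1
  ma <- moving_average(x, 5)
  expect_equal(sum(ma == 0.2, na.rm = TRUE), 5)
  # even windows widen by one bin (centered)
  expect_equal(moving_average(1:10, 4), moving_average(1:10, 5))
  expect_warning(out <- moving_average(1:3, 9), "window longer")
  expect_true(all(is.na(out)))
})

test_that("crossings implement the sign-product rule with zero handling", {
  up <- crossings(c(-1, 1), c(0, 0))
  expect_equal(up$direction, "up")
  expect_equal(up$index, 2L)
  expect_equal(nrow(crossings(c(1, 2, 3), c(0, 0, 0))), 0L)
  cr <- crossings(c(2, -1, -1, 3), c(0, 0, 0, 0))
  expect_equal(cr$index, c(2L, 4L))
  expect_equal(cr$direction, c("down", "up"))
  # zeros are skipped; crossing lands on the first opposite-sign bin
  cr0 <- crossings(c(-1, 0, 0, 2), c(0, 0, 0, 0))
  expect_equal(cr0$index, 4L)
  expect_equal(cr0$direction, "up")
  # zero run without sign change is not a crossing
  expect_equal(nrow(crossings(c(-1, 0, 0, -2), rep(0, 4))), 0L)
})

test_that("markers match the brute-force oracle on short series", {
  for (s in 1:3) {
    ps <- activity_preset("wt_ld", seed = s)
    rec <- generate_activity(ps$params, make_schedule("LD", 2))
    got <- daily_onset_offset(smooth_activity(rec))
    want <- bf_markers(rec$counts)
    expect_equal(got$onset_zt, want$onset_zt, tolerance = 1e-12)
    expect_equal(got$offset_zt, want$offset_zt, tolerance = 1e-12)
  }
})

test_that("noiseless square-wave activity yields onset 12 and offset 24", {
  rate <- rep(0, 3 * 8640)
  zt <- ((seq_along(rate) - 0.5) / 360) %% 24
  counts <- ifelse(zt >= 12, 100, 0)  # deterministic, no rest noise
  sm <- smooth_activity(counts)
  oo <- daily_onset_offset(sm)
  expect_equal(oo$onset_zt[2], 12, tolerance = 0.75)
  expect_equal(oo$offset_zt[2], 24, tolerance = 0.75)
})

test_that("constant activity produces no markers", {
  sm <- smooth_activity(rep(5, 2 * 8640))
  expect_warning(oo <- daily_onset_offset(sm), "no.*crossings")
  expect_true(all(is.na(oo$onset_zt)))
  mid <- daily_midpoint(rep(0, 2 * 8640))
  expect_true(all(is.na(mid$midpoint_zt)))
})

test_that("midpoint finds the 8-h activity balance point", {
  # symmetric block centered at ZT18
  zt <- ((seq_len(3 * 8640) - 0.5) / 360) %% 24
  counts <- ifelse(zt >= 12 & zt < 24, 50, 0)
  mid <- daily_midpoint(counts)
  expect_equal(mid$midpoint_zt[2], 18, tolerance = 0.05)
  # delayed block on ZT [15.6, 27.6)
  h <- (seq_len(3 * 8640) - 0.5) / 360
  counts2 <- ifelse((h - 15.6) %% 24 < 12, 50, 0)
  mid2 <- daily_midpoint(counts2)
  expect_equal(mid2$midpoint_zt[2], 21.6, tolerance = 0.05)
})

test_that("markers are equivariant to time shifts and invariant to scaling", {
  ps <- activity_preset("wt_ld", seed = 9)
  rec <- generate_activity(ps$params, make_schedule("LD", 3))
  base <- phase_markers(rec)
  m <- 720L  # 2 h shift
  shifted <- c(rep(0L, m), rec$counts[seq_len(length(rec$counts) - m)])
  sh <- phase_markers(shifted)
  expect_equal(sh$onset_zt[2], base$onset_zt[2] + 2, tolerance = 0.05)
  expect_equal(sh$midpoint_zt[2], base$midpoint_zt[2] + 2, tolerance = 0.05)
  scaled <- rec$counts * 7L
  sc <- phase_markers(scaled)
  expect_equal(sc$onset_zt, base$onset_zt, tolerance = 1e-9)
  expect_equal(sc$offset_zt, base$offset_zt, tolerance = 1e-9)
  expect_equal(sc$midpoint_zt, base$midpoint_zt, tolerance = 1e-9)
})

test_that("phase delay is zero on identical day sets and tracks sign", {
  ps <- activity_preset("wt_dle", seed = 10)
  tab <- phase_markers(generate_activity(ps$params, ps$schedule))
  d0 <- phase_delay(tab, 2:6, 2:6, "onset_zt")
  expect_equal(d0$mean_h, 0)
  # phase advance gives a negative delay
  adv <- activity_params(psi_target_h = -1, psi_midpoint_h = -1,
                         psi_offset_h = -1, seed = 11)
  sch <- c(make_schedule("LD", 7), make_schedule("DLE", 13))
  tab2 <- phase_markers(generate_activity(adv, sch))
  d2 <- phase_delay(tab2, 2:7, 16:20, "onset_zt")
  expect_lt(d2$mean_h, -0.5)
})

test_that("free-running period comes from the onset drift regression", {
  tab <- data.frame(day = 1:6, onset_zt = 12 + (0:5) * 0.5,
                    midpoint_zt = NA, offset_zt = NA)
  class(tab) <- c("phase_marker_table", "data.frame")
  expect_equal(free_run_period(tab), 24.5, tolerance = 1e-9)
  tab$onset_zt <- rep(13, 6)
  expect_equal(free_run_period(tab), 24, tolerance = 1e-9)
  tab$onset_zt[3:6] <- NA
  expect_warning(expect_true(is.na(free_run_period(tab))), "fewer than 4")
})

test_that("onsets and offsets alternate within days", {
  ps <- activity_preset("wt_dle", seed = 12)
  tab <- phase_markers(generate_activity(ps$params, ps$schedule))
  both <- tab[is.finite(tab$onset_zt) & is.finite(tab$offset_zt), ]
  expect_true(all(both$onset_zt < both$offset_zt))
  expect_true(all(both$onset_zt >= 6 & both$offset_zt < 30))
  ok <- is.finite(tab$onset_zt) & is.finite(tab$midpoint_zt) &
    is.finite(tab$offset_zt)
  expect_true(all(tab$onset_zt[ok] <= tab$midpoint_zt[ok] &
                    tab$midpoint_zt[ok] <= tab$offset_zt[ok]))
})
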