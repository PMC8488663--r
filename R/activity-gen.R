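# Synthetic passive-infrared (PIR) activity generator.
#
# A nocturnal mouse is modelled as a two-state Poisson counting process on
# 10-s bins: a behavioural active window (high rate) covering roughly the
# dark phase and a rest window (low rate) elsewhere. Phase delays induced by
# evening light are imposed on the window edges through a first-order
# re-entrainment recursion; under constant darkness the window drifts by
# (tau - 24) h per day. Sleep is NOT generated separately: it emerges from
# runs of zero counts in the rest state, so activity and sleep are mutually
# consistent, as for real PIR data.

# memoized window calibrations (deterministic, shared across recordings)
.window_cache <- new.env(parent = emptyenv())

# evaluate and restore RNG state around seeded generation
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Parameters for the synthetic activity generator
#'
#' @param lambda_active mean PIR counts per 10-s bin during behavioural
#'   activity (default 2.0).
#' @param lambda_rest mean counts per bin during rest (default 0.15, chosen
#'   so that immobility-defined sleep occupies roughly 0.75 of the light
#'   phase; see the package vignette).
#' @param alpha_h duration of the active period in hours (default 12).
#' @param psi_target_h steady-state phase delay of activity onset relative
#'   to ZT12, in hours, applying on non-baseline (DLE / long-day) days.
#' @param psi_midpoint_h steady-state delay of the activity midpoint
#'   (median of the nightly activity distribution); defaults to the mean of
#'   the onset and offset targets.
#' @param psi_offset_h steady-state delay of activity offset; defaults to
#'   `psi_target_h`.
#' @param psi_init_h phase delay carried into day 1 (e.g. prior lighting
#'   history for constant-darkness recordings), default 0.
#' @param k_reentrain fractional approach to the target delay per day
#'   (default 0.3), in (0, 1].
#' @param masking multiplicative rate factor applied while dim light
#'   (0 < lux < 200) is present, in `[0, 1]` (default 0.8).
#' @param ultradian_depth relative depth of ultradian modulation of the
#'   active-window rate, in `[0, 1]` (default 0).
#' @param ultradian_period_h ultradian period in hours (default 8).
#' @param tau_h free-running period used under constant darkness
#'   (default 23.7).
#' @param phase_jitter_sd_h SD of a rigid day-to-day jitter applied to all
#'   three marker times (hours, default 0). Nonzero values emulate the
#'   day-to-day scatter of onsets seen in single-animal actograms; the
#'   recognition-memory preset uses 1 h so that sleep history varies between
#'   trials of the same type.
#' @param seed integer seed for the jitter and Poisson draws.
#' @return a list of class `activity_params`.
#' @export
activity_params <- function(lambda_active = 2.0, lambda_rest = 0.15,
                            alpha_h = 12, psi_target_h = 0,
                            psi_midpoint_h = NULL, psi_offset_h = NULL,
                            psi_init_h = 0, k_reentrain = 0.3, masking = 0.8,
                            ultradian_depth = 0, ultradian_period_h = 8,
                            tau_h = 23.7, phase_jitter_sd_h = 0,
                            seed = NULL) {
  if (is.null(psi_offset_h)) psi_offset_h <- psi_target_h
  if (is.null(psi_midpoint_h)) psi_midpoint_h <- (psi_target_h + psi_offset_h) / 2
  p <- list(lambda_active = lambda_active, lambda_rest = lambda_rest,
            alpha_h = alpha_h, psi_target_h = psi_target_h,
            psi_midpoint_h = psi_midpoint_h, psi_offset_h = psi_offset_h,
            psi_init_h = psi_init_h, k_reentrain = k_reentrain,
            masking = masking, ultradian_depth = ultradian_depth,
            ultradian_period_h = ultradian_period_h, tau_h = tau_h,
            phase_jitter_sd_h = phase_jitter_sd_h, seed = seed)
  if (!(p$lambda_active > p$lambda_rest) || p$lambda_rest < 0)
    stop("require lambda_active > lambda_rest >= 0")
  if (!(p$k_reentrain > 0 && p$k_reentrain <= 1))
    stop("k_reentrain must be in (0, 1]")
  if (p$masking < 0 || p$masking > 1) stop("masking must be in [0, 1]")
  if (p$ultradian_depth < 0 || p$ultradian_depth > 1)
    stop("ultradian_depth must be in [0, 1]")
  class(p) <- "activity_params"
  p
}

# Deterministic daily phase-delay trajectory for a protocol sequence.
# Returns a days x 3 matrix (onset, midpoint, offset delays in hours).
psi_trajectory <- function(params, protocols) {
  n <- length(protocols)
  tgt <- function(proto) {
    if (proto %in% c("DLE", "LD16_8"))
      c(params$psi_target_h, params$psi_midpoint_h, params$psi_offset_h)
    else c(0, 0, 0)
  }
  psi <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("onset", "midpoint", "offset")))
  state <- rep(params$psi_init_h, 3)
  for (d in seq_len(n)) {
    if (protocols[d] == "DD") {
      state <- state + (params$tau_h - 24)
    } else {
      state <- state + params$k_reentrain * (tgt(protocols[d]) - state)
    }
    psi[d, ] <- state
  }
  psi
}

# Per-bin rate profile for one day tiled periodically, on the 10-s grid.
# a, m, b: onset, median and offset of the active window in hours on the
# day's own axis (a may exceed 24 into the next day); lux_day: per-bin lux.
day_rate <- function(a, m, b, lux_day, params) {
  tmid <- (seq_len(8640L) - 0.5) / 360
  # evaluate window membership on the circle (period 24)
  rel <- (tmid - a) %% 24
  L <- b - a
  rate <- rep(params$lambda_rest, 8640L)
  r1 <- params$lambda_active * L / (2 * (m - a))
  r2 <- params$lambda_active * L / (2 * (b - m))
  in1 <- rel < (m - a)
  in2 <- rel >= (m - a) & rel < L
  rate[in1] <- r1
  rate[in2] <- r2
  if (params$ultradian_depth > 0) {
    inw <- in1 | in2
    rate[inw] <- rate[inw] * (1 + params$ultradian_depth *
      cos(2 * pi * rel[inw] / params$ultradian_period_h))
  }
  dim_light <- lux_day > 0 & lux_day < 200
  rate[dim_light] <- rate[dim_light] * params$masking
  rate
}

# Detect onset/midpoint/offset of a noiseless periodic day rate with the
# same moving-average crossing and 8-h balance rules the analysis uses.
detect_noiseless <- function(rate_day) {
  x <- rep(rate_day, 3)
  base <- moving_average(x, 360L)
  short <- moving_average(base, 1080L)
  long <- moving_average(base, 8640L)
  cr <- crossings(short, long)
  mid_day <- cr$index > 8640 & cr$index <= 17280
  h <- (cr$index - 0.5) / 360 - 24
  on <- h[mid_day & cr$direction == "up"][1]
  offs <- h[mid_day & cr$direction == "down"]
  off <- if (length(offs)) offs[length(offs)] else NA_real_
  if (is.finite(on) && is.finite(off) && off < on) off <- off + 24
  cs <- cumsum(c(0, x))
  i <- 2881:(length(x) - 2880 + 1)
  before <- cs[i] - cs[i - 2880]
  after <- cs[i + 2880] - cs[i]
  cb <- crossings(before - after, rep(0, length(i)))
  cb <- cb[cb$direction == "up", , drop = FALSE]
  hm <- (cb$index + 2880 - 0.5) / 360 - 24
  mid <- hm[hm >= 0 & hm < 24][1]
  c(onset = on, midpoint = mid, offset = off)
}

# Solve for window edges (a, m, b) such that the markers detected on the
# noiseless rate land on the programmed times (A, M, B). The detection
# rules respond smoothly to the edges, so a few fixed-point sweeps suffice.
calibrate_window <- function(A, M, B, lux_day, params, iter = 4) {
  a <- A; m <- M; b <- B
  for (k in seq_len(iter)) {
    det <- detect_noiseless(day_rate(a, m, b, lux_day, params))
    if (anyNA(det)) break
    a <- a + (A - det["onset"])
    m <- m + (M - det["midpoint"])
    b <- b + (B - det["offset"])
    if (!(a < m && m < b)) {  # give up: keep programmed geometry
      a <- A; m <- M; b <- B
      break
    }
  }
  c(a = unname(a), m = unname(m), b = unname(b))
}

#' Generate a synthetic PIR activity recording
#'
#' Draws 10-s binned Poisson counts under the two-state rate model described
#' in [activity_params()], following the given lighting schedule. The daily
#' phase delay follows the first-order recursion
#' `psi_{d+1} = psi_d + k * (psi_target - psi_d)` after a protocol switch
#' (closed form `psi_d = psi_target * (1 - (1 - k)^d)` from a zero start),
#' and advances by `tau_h - 24` hours per day under constant darkness.
#' Ground-truth daily marker times are stored alongside the counts.
#'
#' @param params an `activity_params` object.
#' @param schedule a `light_schedule`.
#' @return an object of class `activity_recording`: a list with elements
#'   `counts` (integer, 8640 per day), `bin_width_s` (10), `start_zt` (0),
#'   `schedule`, `ground_truth` (per-day true onset/midpoint/offset, ZT
#'   hours on the day's own axis) and `params`.
#' @export
generate_activity <- function(params, schedule) {
  stopifnot(inherits(params, "activity_params"),
            inherits(schedule, "light_schedule"))
  protocols <- attr(schedule, "protocols")
  n_days <- attr(schedule, "n_days")
  psi <- psi_trajectory(params, protocols)
  bins_per_day <- 8640L
  n <- n_days * bins_per_day
  tmid <- (seq_len(n) - 0.5) * (10 / 3600)  # hours since recording start

  gen <- with_seed(params$seed, {
    # day-to-day phase jitter (rigid shift of all three markers); drawn
    # before the Poisson stream so both come from one seed
    jitter <- if (params$phase_jitter_sd_h > 0)
      stats::rnorm(n_days, 0, params$phase_jitter_sd_h) else numeric(n_days)
    truth <- data.frame(day = seq_len(n_days),
                        psi_onset = psi[, 1] + jitter,
                        psi_midpoint = psi[, 2] + jitter,
                        psi_offset = psi[, 3] + jitter,
                        onset_zt = 12 + psi[, 1] + jitter,
                        midpoint_zt = 12 + params$alpha_h / 2 + psi[, 2] +
                          jitter,
                        offset_zt = 12 + params$alpha_h + psi[, 3] + jitter)
    rate <- rep(params$lambda_rest, n)
    lux <- lux_at(schedule, tmid)
    # The moving-average crossing and 8-h balance rules detect markers with
    # a geometry-dependent offset from the raw window edges (the crossing
    # level depends on the window's duty cycle). Window edges are therefore
    # calibrated per day so that the markers detectable on the noiseless
    # rate land exactly on the ground-truth times; the day's jitter is a
    # rigid time shift, so the calibration (memoized on the un-jittered
    # geometry) is shifted along with it.
    geom <- paste(params$lambda_active, params$lambda_rest, params$masking,
                  params$ultradian_depth, params$ultradian_period_h)
    for (d in seq_len(n_days)) {
      A <- 12 + psi[d, 1]
      M <- 12 + params$alpha_h / 2 + psi[d, 2]
      B <- 12 + params$alpha_h + psi[d, 3]
      if (!(A < M && M < B))
        stop("midpoint target outside the active window on day ", d)
      key <- paste(geom, protocols[d], round(A, 4), round(M, 4), round(B, 4))
      if (is.null(.window_cache[[key]])) {
        lux_day <- lux_at(schedule, (seq_len(8640L) - 0.5) / 360 +
                            24 * (d - 1))
        .window_cache[[key]] <- calibrate_window(A, M, B, lux_day, params)
      }
      wc <- .window_cache[[key]] + jitter[d]
      a <- 24 * (d - 1) + wc["a"]
      m <- 24 * (d - 1) + wc["m"]
      b <- 24 * (d - 1) + wc["b"]
      L <- b - a
      r1 <- params$lambda_active * L / (2 * (m - a))
      r2 <- params$lambda_active * L / (2 * (b - m))
      in1 <- tmid >= a & tmid < m
      in2 <- tmid >= m & tmid < b
      rate[in1] <- r1
      rate[in2] <- r2
      if (params$ultradian_depth > 0) {
        inw <- in1 | in2
        rate[inw] <- rate[inw] *
          (1 + params$ultradian_depth *
             cos(2 * pi * (tmid[inw] - a) / params$ultradian_period_h))
      }
    }
    dim_light <- lux > 0 & lux < 200
    rate[dim_light] <- rate[dim_light] * params$masking
    list(truth = truth, counts = stats::rpois(n, rate))
  })
  truth <- gen$truth
  counts <- gen$counts
  structure(list(counts = as.integer(counts), bin_width_s = 10L,
                 start_zt = 0, schedule = schedule, ground_truth = truth,
                 params = params),
            class = "activity_recording")
}

#' @export
print.activity_recording <- function(x, ...) {
  nd <- attr(x$schedule, "n_days")
  cat("PIR activity recording:", nd, "day(s),",
      length(x$counts), "x 10-s bins\n")
  r <- rle(attr(x$schedule, "protocols"))
  cat("Schedule:", paste(sprintf("%d d %s", r$lengths, r$values),
                         collapse = " + "), "\n")
  cat("Mean count/bin:", round(mean(x$counts), 3), "\n")
  invisible(x)
}

#' Study presets for the activity generator
#'
#' Returns the generator parameters and lighting schedule emulating one of
#' the study arms: wild-type DLE, melanopsin-knockout DLE, long-day 16:8,
#' and constant darkness after LD or DLE history. Steady-state marker delay
#' targets are the group means reported for the corresponding arm (onset /
#' midpoint / offset: 3.59 / 2.57 / 2.52 h for wild type under DLE,
#' 2.74 / 2.32 / 1.61 h for Opn4-deficient mice, and an extra
#' 2.21 / 0.99 / 0.64 h under the 16:8 long day).
#'
#' @param preset one of `"wt_ld"`, `"wt_dle"`, `"opn4_dle"`, `"ld16_8"`,
#'   `"dd_prior_ld"`, `"dd_prior_dle"`.
#' @param seed integer seed placed in the returned params.
#' @param ultradian_depth optional ultradian modulation depth override.
#' @return list with elements `params` (`activity_params`) and `schedule`
#'   (`light_schedule`).
#' @export
activity_preset <- function(preset = c("wt_ld", "wt_dle", "opn4_dle",
                                       "ld16_8", "dd_prior_ld",
                                       "dd_prior_dle"),
                            seed = NULL, ultradian_depth = 0) {
  preset <- match.arg(preset)
  base <- function(...) activity_params(..., seed = seed,
                                        ultradian_depth = ultradian_depth)
  switch(preset,
    wt_ld = list(params = base(),
                 schedule = make_schedule("LD", 20)),
    wt_dle = list(params = base(psi_target_h = 3.59, psi_midpoint_h = 2.57,
                                psi_offset_h = 2.52),
                  schedule = c(make_schedule("LD", 7),
                               make_schedule("DLE", 13))),
    opn4_dle = list(params = base(psi_target_h = 2.74, psi_midpoint_h = 2.32,
                                  psi_offset_h = 1.61),
                    schedule = c(make_schedule("LD", 7),
                                 make_schedule("DLE", 13))),
    ld16_8 = list(params = base(psi_target_h = 3.59 + 2.21,
                                psi_midpoint_h = 2.57 + 0.99,
                                psi_offset_h = 2.52 + 0.64),
                  schedule = c(make_schedule("LD", 7),
                               make_schedule("LD16_8", 13))),
    dd_prior_ld = list(params = base(psi_init_h = 0, tau_h = 23.7),
                       schedule = make_schedule("DD", 5)),
    dd_prior_dle = list(params = base(psi_init_h = 4.0, tau_h = 23.7),
                        schedule = make_schedule("DD", 5))
  )
}

#' Simulate a cohort of activity recordings
#'
#' @param preset an [activity_preset()] name.
#' @param n_animals number of mice.
#' @param seed base seed; each animal gets a fixed-offset child seed.
#' @param ... passed to [activity_preset()].
#' @return list of `activity_recording`, one per animal.
#' @export
simulate_cohort <- function(preset, n_animals = 12, seed = 1, ...) {
  lapply(seq_len(n_animals), function(i) {
    ps <- activity_preset(preset, seed = child_seed(seed, i), ...)
    generate_activity(ps$params, ps$schedule)
  })
}
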