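# Synthetic shutter-gated in vivo bioluminescence.
#
# A photomultiplier records per-minute photon counts from a hepatic
# luciferase reporter; a programmable shutter closes for 1 minute in every
# 15 to sample the background. Open-shutter counts are Poisson around a slow
# background drift plus a half-wave-rectified circadian signal; closed
# minutes see the background only.

#' Generate a shutter-gated bioluminescence trace
#'
#' Open-shutter counts are
#' `Poisson(B(t) + A * max(0, 1 + cos(2 pi (t - phi) / tau)))` and
#' closed-shutter counts `Poisson(B(t))`, where `B(t)` is a linear-plus-slow-
#' sinusoidal background drift. Minute 15, 30, 45, ... of every quarter hour
#' is shutter-closed (one closed minute per 15-minute block).
#'
#' @param phi_true acrophase of the circadian signal, hours.
#' @param tau_true period, hours.
#' @param days recording length in days (>= 2).
#' @param amplitude signal amplitude `A` in counts/min (default 400).
#' @param background mean background in counts/min (default 300, > 0).
#' @param bg_slope linear background drift in counts/min per day (default 5).
#' @param bg_sin_amp amplitude of a slow (72-h) background oscillation
#'   (default 20).
#' @param seed integer seed.
#' @return object of class `biolum_trace`: list with per-minute `counts`,
#'   logical `shutter_open`, `minute` (0-based), and the ground truth
#'   (`phi_true`, `tau_true`, background parameters).
#' @export
generate_bioluminescence <- function(phi_true, tau_true = 24, days = 5,
                                     amplitude = 400, background = 300,
                                     bg_slope = 5, bg_sin_amp = 20,
                                     seed = NULL) {
  if (days < 2) stop("need days >= 2")
  if (amplitude < 0 || background <= 0)
    stop("amplitude must be >= 0 and background > 0")
  n <- as.integer(days * 24 * 60)
  minute <- seq_len(n) - 1L
  t_h <- minute / 60
  open <- (minute %% 15L) != 14L  # last minute of each 15-min block closed
  bg <- background + bg_slope * t_h / 24 +
    bg_sin_amp * sin(2 * pi * t_h / 72)
  sig <- amplitude * pmax(0, 1 + cos(2 * pi * (t_h - phi_true) / tau_true))
  rate <- bg + ifelse(open, sig, 0)
  counts <- with_seed(seed, stats::rpois(n, rate))
  structure(list(counts = counts, shutter_open = open, minute = minute,
                 phi_true = phi_true, tau_true = tau_true,
                 amplitude = amplitude, background = background,
                 bg_slope = bg_slope, bg_sin_amp = bg_sin_amp),
            class = "biolum_trace")
}

#' @export
print.biolum_trace <- function(x, ...) {
  cat("Shutter-gated bioluminescence trace:",
      length(x$counts) / 1440, "day(s)\n")
  cat(sprintf("Ground truth: phi = %.2f h, tau = %.2f h, A = %g\n",
              x$phi_true, x$tau_true, x$amplitude))
  invisible(x)
}
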