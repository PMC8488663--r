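# Bioluminescence rhythm analysis: shutter-based background correction,
# circadian-band wavelet detrending, per-cycle acrophase, signal-to-noise
# ratio, and period estimation. Analysis runs at 15-min resolution after
# block-averaging open-shutter minutes, which stabilizes Poisson noise.

#' Background-correct a shutter-gated trace
#'
#' The background is linearly interpolated between closed-shutter minutes
#' and subtracted from the raw counts at open minutes; corrected values at
#' closed minutes are filled by linear interpolation of the corrected
#' series. Correction is exact in expectation for backgrounds that are
#' piecewise linear between closed minutes.
#'
#' @param trace a `biolum_trace` (or list with `counts`, `shutter_open`,
#'   `minute`).
#' @return list of class `corrected_trace`: per-minute `corrected`,
#'   `background` (interpolated), `minute`, `open`.
#' @export
background_correct <- function(trace) {
  open <- trace$shutter_open
  if (!any(!open)) stop("no closed-shutter minutes; cannot estimate background")
  minute <- trace$minute
  mc <- minute[!open]
  yc <- trace$counts[!open]
  bg <- stats::approx(mc, yc, xout = minute, rule = 2)$y
  # linear extrapolation beyond the first/last closed minute (constant
  # extrapolation would bias the ends under a drifting background)
  if (length(mc) >= 2) {
    head_i <- minute < mc[1]
    s1 <- (yc[2] - yc[1]) / (mc[2] - mc[1])
    bg[head_i] <- yc[1] + s1 * (minute[head_i] - mc[1])
    k <- length(mc)
    tail_i <- minute > mc[k]
    s2 <- (yc[k] - yc[k - 1]) / (mc[k] - mc[k - 1])
    bg[tail_i] <- yc[k] + s2 * (minute[tail_i] - mc[k])
  }
  corrected <- trace$counts - bg
  corrected[!open] <- stats::approx(minute[open], corrected[open],
                                    xout = minute[!open], rule = 2)$y
  structure(list(corrected = corrected, background = bg, minute = minute,
                 open = open),
            class = "corrected_trace")
}

# Average a per-minute corrected trace into 15-min blocks (hours at block
# centers returned alongside).
block_average_15min <- function(ct) {
  n <- length(ct$corrected)
  k <- floor(n / 15)
  idx <- rep(seq_len(k), each = 15)
  y <- as.numeric(tapply(ct$corrected[seq_len(k * 15)], idx, mean))
  list(y = y, t_h = (seq_len(k) - 0.5) * 0.25, dt_h = 0.25)
}

#' Circadian-band wavelet detrending
#'
#' Multiresolution MODWT decomposition (LA(8), reflection boundary) of the
#' background-corrected trace at 15-min resolution; returns the
#' reconstruction from the detail levels whose pass-band covers 16-32 h,
#' which removes both the slow trend (> 32 h) and high-frequency noise
#' (< 16 h).
#'
#' @param ct a `corrected_trace` from [background_correct()], or a list with
#'   elements `y` (series) and `dt_h` (sampling step in hours).
#' @return list of class `detrended_rhythm`: `y` (circadian-band series),
#'   `t_h` (hours), `dt_h`.
#' @export
dwt_detrend <- function(ct) {
  ba <- if (inherits(ct, "corrected_trace")) block_average_15min(ct)
        else ct
  if (length(ba$y) * ba$dt_h < 48)
    stop("trace shorter than 2 days; circadian band unresolvable")
  lev <- levels_for_band(ba$dt_h, 16, 32)
  J <- max(lev)
  if (2^J > length(ba$y))
    stop("trace too short for the required decomposition depth (need >= ",
         2^J, " samples at ", ba$dt_h, " h)")
  mra <- modwt_mra(ba$y, J)
  y <- Reduce(`+`, mra$details[lev])
  structure(list(y = y, t_h = if (is.null(ba$t_h))
    (seq_along(y) - 0.5) * ba$dt_h else ba$t_h, dt_h = ba$dt_h),
    class = "detrended_rhythm")
}

# per-cycle peak times of a band-limited series: local maxima separated by
# at least min_sep_h. Peaks within edge_h of either end are discarded: the
# reflection boundary of the wavelet reconstruction distorts extrema there.
cycle_peaks <- function(y, t_h, min_sep_h = 16, edge_h = 12) {
  n <- length(y)
  loc <- which(diff(sign(diff(y))) < 0) + 1L
  loc <- loc[y[loc] > 0]
  loc <- loc[t_h[loc] >= t_h[1] + edge_h & t_h[loc] <= t_h[n] - edge_h]
  if (!length(loc)) return(numeric(0))
  # enforce separation, keeping the higher peak
  keep <- integer(0)
  for (i in loc) {
    if (length(keep) && t_h[i] - t_h[keep[length(keep)]] < min_sep_h) {
      if (y[i] > y[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  # sub-bin refinement: parabola through the peak and its neighbours
  vapply(keep, function(i) {
    if (i <= 1L || i >= n) return(t_h[i])
    den <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (den >= 0) return(t_h[i])
    t_h[i] + 0.5 * (y[i - 1] - y[i + 1]) / den * (t_h[2] - t_h[1])
  }, numeric(1))
}

#' Acrophase of a detrended circadian rhythm
#'
#' The acrophase is the circular mean of per-cycle peak times of the
#' circadian-band reconstruction, expressed in external clock hours
#' (mod 24).
#'
#' @param detrended a `detrended_rhythm` from [dwt_detrend()], or a
#'   `corrected_trace` (detrended on the fly).
#' @return list of class `rhythm_estimate`: `phi_h` in `[0, 24)`,
#'   `peaks_h` (per-cycle peak times, hours since start), `n_cycles`.
#' @export
acrophase <- function(detrended) {
  if (inherits(detrended, "corrected_trace"))
    detrended <- dwt_detrend(detrended)
  pk <- cycle_peaks(detrended$y, detrended$t_h)
  if (!length(pk)) {
    warning("no cycle peaks detected; acrophase undefined")
    return(structure(list(phi_h = NA_real_, peaks_h = numeric(0),
                          n_cycles = 0L), class = "rhythm_estimate"))
  }
  structure(list(phi_h = circular_mean_hours(pk %% 24),
                 peaks_h = pk, n_cycles = length(pk)),
            class = "rhythm_estimate")
}

#' @export
print.rhythm_estimate <- function(x, ...) {
  cat(sprintf("Rhythm acrophase: %.2f h (circular mean of %d cycle peaks)\n",
              x$phi_h, x$n_cycles))
  invisible(x)
}

#' Rhythm signal-to-noise ratio
#'
#' Variance of the circadian-band (16-32 h) MODWT reconstruction divided by
#' the variance of the high-frequency (< 4 h) reconstruction.
#'
#' @param ct a `corrected_trace`.
#' @return non-negative SNR; `Inf` when the noise band has zero variance.
#' @export
rhythm_snr <- function(ct) {
  ba <- block_average_15min(ct)
  lev_sig <- levels_for_band(ba$dt_h, 16, 32)
  lev_noise <- seq_len(min(levels_for_band(ba$dt_h, 16, 32)) - 1)
  lev_noise <- lev_noise[2^(lev_noise + 1) * ba$dt_h <= 4 + 1e-9]
  mra <- modwt_mra(ba$y, max(lev_sig))
  v_sig <- stats::var(Reduce(`+`, mra$details[lev_sig]))
  v_noise <- stats::var(Reduce(`+`, mra$details[lev_noise]))
  if (v_noise == 0) return(Inf)
  v_sig / v_noise
}

#' Period from per-cycle acrophases
#'
#' The period is 24 h plus the least-squares slope of the unwrapped
#' per-cycle acrophase (clock hours) against cycle index, consistent with
#' the free-running period estimator for activity onsets.
#'
#' @param detrended a `detrended_rhythm` or `corrected_trace`.
#' @return period in hours, `NA` when fewer than 3 cycle peaks are found.
#' @export
estimate_period <- function(detrended) {
  if (inherits(detrended, "corrected_trace"))
    detrended <- dwt_detrend(detrended)
  pk <- cycle_peaks(detrended$y, detrended$t_h)
  if (length(pk) < 3) {
    warning("fewer than 3 cycles; period undefined")
    return(NA_real_)
  }
  cyc <- seq_along(pk)
  phase <- unwrap_series(pk %% 24)
  fit <- stats::lm(phase ~ cyc)
  24 + unname(stats::coef(fit)[2])
}

#' Wavelet power spectrum of locomotor activity
#'
#' Rebins a PIR recording to 6-min resolution and computes the Morlet
#' continuous-wavelet power averaged over time (cone of influence excluded)
#' on a period grid spanning at least 4-32 h; the powers at 24 h and 8 h
#' are reported for the circadian and ultradian components.
#'
#' @param recording an `activity_recording`.
#' @param periods_h period grid in hours.
#' @return a `wavelet_power` data frame with attribute `power_24h` and
#'   `power_8h` (grid values closest to 24 h and 8 h).
#' @export
cwt_power <- function(recording,
                      periods_h = exp(seq(log(4), log(32), length.out = 48))) {
  counts <- if (inherits(recording, "activity_recording"))
    recording$counts else recording
  if (length(counts) < 4 * 8640) stop("need at least 4 days of activity")
  k <- floor(length(counts) / 36)
  y <- as.numeric(tapply(counts[seq_len(k * 36)],
                         rep(seq_len(k), each = 36), sum))
  ps <- morlet_power(y, dt_h = 0.1, periods_h = periods_h)
  attr(ps, "power_24h") <- ps$power[which.min(abs(ps$period_h - 24))]
  attr(ps, "power_8h") <- ps$power[which.min(abs(ps$period_h - 8))]
  ps
}
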