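# Locomotor phase markers from moving-average crossings.
#
# Raw 10-s PIR counts are smoothed with a 1-h moving average; activity onset
# and offset on each day are the intersections of a short (3-h) and a long
# (24-h) moving average of the smoothed series. The midpoint is the time at
# which total activity in the preceding 8 h equals total activity in the
# subsequent 8 h. Markers are assigned to day windows spanning ZT 6-30 so
# the nocturnal bout is not split at midnight.

#' Centered moving average
#'
#' @param series numeric vector.
#' @param window_bins window length in bins; even values are widened by one
#'   bin so the window is centered.
#' @return vector of the same length; positions where the full window does
#'   not fit are `NA` (no zero-padding).
#' @export
moving_average <- function(series, window_bins) {
  stopifnot(window_bins >= 1)
  w <- as.integer(window_bins)
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(series)
  if (w > n) {
    warning("window longer than series; all values undefined")
    return(rep(NA_real_, n))
  }
  # running mean via cumulative sums: O(n) regardless of window size.
  # NA margins (from prior smoothing passes) shrink the defined range.
  x <- as.numeric(series)
  fin <- which(is.finite(x))
  out <- rep(NA_real_, n)
  if (!length(fin)) return(out)
  a <- fin[1L]; b <- fin[length(fin)]
  core <- x[a:b]
  m <- length(core)
  if (w > m || anyNA(core)) {
    out[a:b] <- as.numeric(stats::filter(core, rep(1 / w, w), sides = 2))
    return(out)
  }
  cs <- cumsum(c(0, core))
  h <- (w - 1L) %/% 2L
  i <- (h + 1L):(m - h)
  out[a + i - 1L] <- (cs[i + h + 1L] - cs[i - h]) / w
  out
}

#' Sign-change crossings of a short-minus-long difference series
#'
#' With `delta[i] = short[i] - long[i]`, an upward crossing occurs at `i`
#' when `delta[i-1] * delta[i] < 0` with `delta[i-1] < 0`, a downward
#' crossing when `delta[i-1] > 0`. Runs of exact zeros are skipped: the
#' crossing is registered at the first bin where `delta` becomes nonzero
#' with sign opposite to the last nonzero value.
#'
#' @param short,long aligned numeric series (`NA` allowed at the margins).
#' @return data frame with columns `index` (bin of the crossing) and
#'   `direction` (`"up"` or `"down"`); zero rows if no crossing exists.
#' @export
crossings <- function(short, long) {
  stopifnot(length(short) == length(long))
  delta <- short - long
  s <- sign(delta)
  valid <- which(is.finite(delta) & s != 0)
  if (length(valid) < 2L)
    return(data.frame(index = integer(0), direction = character(0),
                      stringsAsFactors = FALSE))
  sv <- s[valid]
  chg <- which(sv[-1L] != sv[-length(sv)]) + 1L
  data.frame(index = valid[chg],
             direction = ifelse(sv[chg - 1L] < 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Smooth a PIR recording for phase-marker extraction
#'
#' @param recording an `activity_recording` (or a bare numeric count vector
#'   at 10-s resolution).
#' @return list of class `smoothed_activity` with the 1-h smoothed `base`
#'   series, the 3-h `short` and 24-h `long` moving averages of it, and the
#'   bin width in seconds.
#' @export
smooth_activity <- function(recording) {
  counts <- if (inherits(recording, "activity_recording"))
    recording$counts else recording
  base <- moving_average(counts, 360L)     # 1 h of 10-s bins
  structure(list(base = base,
                 short = moving_average(base, 1080L),   # 3 h
                 long = moving_average(base, 8640L),    # 24 h
                 bin_width_s = 10L, n = length(counts)),
            class = "smoothed_activity")
}

# bin index -> hours since recording start (bin centers)
bin_hours <- function(i, bin_width_s = 10) (i - 0.5) * bin_width_s / 3600

# day windows on the ZT 6-30 axis: day d covers absolute hours
# [24 (d-1) + 6, 24 (d-1) + 30)
marker_day <- function(hours) floor((hours - 6) / 24) + 1

#' Daily activity onsets and offsets
#'
#' Onset on each day is the first upward short/long crossing within the
#' day's ZT 6-30 window; offset is the last downward crossing after it.
#' Times are continuous ZT hours on the day's own axis, in `[6, 30)`.
#'
#' @param sm a `smoothed_activity` from [smooth_activity()].
#' @return data frame `day`, `onset_zt`, `offset_zt` (NA when missing).
#' @export
daily_onset_offset <- function(sm) {
  stopifnot(inherits(sm, "smoothed_activity"))
  n_days <- sm$n / 8640
  if (n_days < 2) stop("need at least 2 days of data")
  cr <- crossings(sm$short, sm$long)
  out <- data.frame(day = seq_len(floor(n_days)),
                    onset_zt = NA_real_, offset_zt = NA_real_)
  if (nrow(cr) == 0L) {
    warning("no short/long moving-average crossings found")
    return(out)
  }
  h <- bin_hours(cr$index, sm$bin_width_s)
  d <- marker_day(h)
  zt <- h - 24 * (d - 1)
  for (dd in out$day) {
    up <- which(d == dd & cr$direction == "up")
    if (length(up)) {
      out$onset_zt[dd] <- zt[up[1]]
      down <- which(d == dd & cr$direction == "down" & zt > zt[up[1]])
      if (length(down)) out$offset_zt[dd] <- zt[down[length(down)]]
    }
  }
  out
}

#' Daily activity midpoints by the 8-h balance rule
#'
#' The midpoint is the bin at which total activity in the preceding 8 h
#' first exceeds total activity in the subsequent 8 h (sign change of the
#' before-minus-after difference from negative to positive), assigned to
#' ZT 6-30 day windows as for onsets.
#'
#' @param recording an `activity_recording` or raw count vector.
#' @return data frame `day`, `midpoint_zt` (NA where the 8-h margins do not
#'   fit or no balance point exists).
#' @export
daily_midpoint <- function(recording) {
  counts <- if (inherits(recording, "activity_recording"))
    recording$counts else recording
  n <- length(counts)
  w <- 2880L  # 8 h of 10-s bins
  n_days <- floor(n / 8640)
  out <- data.frame(day = seq_len(n_days), midpoint_zt = NA_real_)
  if (n < 2 * w + 2) return(out)
  cs <- cumsum(as.numeric(counts))
  # before(i) = sum over bins [i - w, i - 1]; after(i) = sum over [i, i + w - 1]
  i <- (w + 1):(n - w + 1)
  before <- cs[i - 1] - c(0, cs)[i - w]
  after <- cs[i + w - 1] - cs[i - 1]
  delta <- before - after
  cr <- crossings(delta, rep(0, length(delta)))
  cr <- cr[cr$direction == "up", , drop = FALSE]
  if (nrow(cr) == 0L) return(out)
  h <- bin_hours(cr$index + w, 10)
  d <- marker_day(h)
  zt <- h - 24 * (d - 1)
  for (dd in out$day) {
    hit <- which(d == dd)
    if (length(hit)) out$midpoint_zt[dd] <- zt[hit[1]]
  }
  out
}

#' Full per-day phase-marker table for one animal
#'
#' @param recording an `activity_recording`.
#' @return data frame of class `phase_marker_table`: `day`, `onset_zt`,
#'   `midpoint_zt`, `offset_zt`, all continuous ZT hours in `[6, 30)`.
#' @export
phase_markers <- function(recording) {
  sm <- smooth_activity(recording)
  oo <- daily_onset_offset(sm)
  mid <- daily_midpoint(recording)
  out <- merge(oo, mid, by = "day", all = TRUE)
  out <- out[, c("day", "onset_zt", "midpoint_zt", "offset_zt")]
  class(out) <- c("phase_marker_table", "data.frame")
  out
}

#' Phase delay between two day sets
#'
#' Per animal, the delay is the mean marker time over the treatment days
#' minus the mean over the baseline days, after unwrapping the per-animal
#' marker sequence (successive days kept within +/- 12 h). The group
#' estimate is the mean and SEM over animals.
#'
#' @param markers a `phase_marker_table` or a list of them (one per animal).
#' @param baseline_days,treatment_days integer day indices.
#' @param marker `"onset_zt"`, `"midpoint_zt"` or `"offset_zt"`.
#' @return list of class `phase_delay`: `mean_h`, `sem_h`, `per_animal`,
#'   `marker`, `n`.
#' @export
phase_delay <- function(markers, baseline_days, treatment_days,
                        marker = c("onset_zt", "midpoint_zt", "offset_zt")) {
  marker <- match.arg(marker)
  stopifnot(length(baseline_days) > 0, length(treatment_days) > 0)
  if (inherits(markers, "phase_marker_table")) markers <- list(markers)
  per <- vapply(markers, function(tab) {
    x <- unwrap_series(tab[[marker]])
    b <- x[tab$day %in% baseline_days]
    t <- x[tab$day %in% treatment_days]
    b <- b[is.finite(b)]; t <- t[is.finite(t)]
    if (!length(b) || !length(t)) return(NA_real_)
    mean(t) - mean(b)
  }, numeric(1))
  if (anyNA(per))
    warning(sum(is.na(per)), " animal(s) without valid markers excluded")
  ok <- per[is.finite(per)]
  structure(list(mean_h = mean(ok), sem_h = sem(ok), per_animal = per,
                 marker = marker, n = length(ok)),
            class = "phase_delay")
}

#' @export
print.phase_delay <- function(x, ...) {
  cat(sprintf("Phase delay (%s): %.2f +/- %.2f h (n = %d)\n",
              sub("_zt", "", x$marker), x$mean_h, x$sem_h, x$n))
  invisible(x)
}

#' Free-running period from daily onsets
#'
#' Under constant darkness the endogenous period is estimated as 24 h plus
#' the least-squares slope of the unwrapped daily onset time against day
#' index.
#'
#' @param markers a `phase_marker_table` restricted to DD days.
#' @param marker which marker column to regress (default onset).
#' @return tau in hours, or `NA` with a warning when fewer than 4 valid
#'   markers exist.
#' @export
free_run_period <- function(markers, marker = "onset_zt") {
  x <- unwrap_series(markers[[marker]])
  keep <- is.finite(x)
  if (sum(keep) < 4) {
    warning("fewer than 4 valid onsets; free-running period undefined")
    return(NA_real_)
  }
  fit <- stats::lm(x[keep] ~ markers$day[keep])
  24 + unname(stats::coef(fit)[2])
}
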