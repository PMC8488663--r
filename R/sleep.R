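# Immobility-defined sleep scoring.
#
# A 10-s PIR bin is scored asleep (1) iff it belongs to a maximal run of
# zero-count bins of length >= 4 (i.e. >= 40 s of sustained immobility);
# otherwise awake (0).

#' Score immobility-defined sleep
#'
#' @param recording an `activity_recording` or an integer count vector at
#'   10-s resolution.
#' @return integer vector of class `sleep_series` (0 = awake, 1 = asleep),
#'   same length as the counts, with attribute `bin_width_s`.
#' @examples
#' score_sleep(c(0, 0, 0, 0))          # all asleep
#' score_sleep(c(0, 0, 0, 2, 0, 0, 0)) # all awake: runs of 3 only
#' @export
score_sleep <- function(recording) {
  counts <- if (inherits(recording, "activity_recording"))
    recording$counts else recording
  zero <- counts == 0
  r <- rle(zero)
  asleep <- r$values & r$lengths >= 4L
  state <- inverse.rle(list(lengths = r$lengths, values = as.integer(asleep)))
  structure(as.integer(state), class = "sleep_series", bin_width_s = 10L)
}

#' Sleep proportion in a window
#'
#' @param series a `sleep_series`.
#' @param from_bin,to_bin window as 1-based bin indices, inclusive; defaults
#'   to the full series.
#' @return fraction of bins asleep in the window, in `[0, 1]`.
#' @export
sleep_proportion <- function(series, from_bin = 1L, to_bin = length(series)) {
  if (to_bin < from_bin || from_bin < 1L || to_bin > length(series))
    stop("empty or out-of-range window")
  mean(unclass(series)[from_bin:to_bin])
}

#' Sleep bouts
#'
#' @param series a `sleep_series`.
#' @return data frame `start_bin`, `length_bins`, `duration_s` of every
#'   maximal run of sleep (by construction every bout lasts >= 40 s).
#' @export
sleep_bouts <- function(series) {
  r <- rle(unclass(series) == 1L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_bin = starts[keep], length_bins = r$lengths[keep],
             duration_s = 10L * r$lengths[keep])
}

#' Binned sleep summary
#'
#' Sleep proportion, bout count and mean bout duration per fixed-width ZT
#' bin (default 4 h). Proportions use per-bin membership of each 10-s bin;
#' each bout is assigned to the bin containing its onset for the duration
#' statistic, so proportions stay exact while durations stay interpretable.
#'
#' @param series a `sleep_series`.
#' @param bin_hours summary bin width in hours (default 4).
#' @return data frame of class `sleep_summary`: `bin_start_h`, `proportion`,
#'   `bout_count`, `mean_bout_s` (NA in bins without a bout onset).
#' @export
binned_sleep_summary <- function(series, bin_hours = 4) {
  n <- length(series)
  bins_per <- as.integer(bin_hours * 360)
  if (n < bins_per) stop("recording shorter than one summary bin")
  k <- floor(n / bins_per)
  idx <- rep(seq_len(k), each = bins_per)
  state <- unclass(series)[seq_len(k * bins_per)]
  prop <- tapply(state, idx, mean)
  bouts <- sleep_bouts(series)
  bbin <- floor((bouts$start_bin - 1) / bins_per) + 1
  keep <- bbin <= k
  cnt <- tabulate(bbin[keep], nbins = k)
  mdur <- rep(NA_real_, k)
  if (any(keep)) {
    agg <- tapply(bouts$duration_s[keep], bbin[keep], mean)
    mdur[as.integer(names(agg))] <- agg
  }
  structure(data.frame(bin_start_h = (seq_len(k) - 1) * bin_hours,
                       proportion = as.numeric(prop), bout_count = cnt,
                       mean_bout_s = mdur),
            class = c("sleep_summary", "data.frame"))
}

#' Sleep proportion in a window preceding an event
#'
#' @param series a `sleep_series`.
#' @param event_h event time in hours since recording start.
#' @param width_h window width in hours; the window is
#'   `[event_h - width_h, event_h)`.
#' @return sleep proportion, or `NA` when the window extends before the
#'   recording start.
#' @export
prior_sleep <- function(series, event_h, width_h) {
  bins_per_h <- 3600 / attr(series, "bin_width_s")
  to <- floor(event_h * bins_per_h)           # last bin before the event
  from <- to - as.integer(round(width_h * bins_per_h)) + 1L
  if (from < 1L || to < from) return(NA_real_)
  sleep_proportion(series, from, to)
}
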