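#' Double-plotted actogram
#'
#' Raster QC plot of a PIR recording with 48-h rows on the ZT 6-30 axis
#' (each row shows the day and the day after), brighter = more activity.
#'
#' @param x an `activity_recording`.
#' @param bin_min raster bin width in minutes (default 6).
#' @param ... passed to [graphics::image()].
#' @export
plot.activity_recording <- function(x, bin_min = 6, ...) {
  per_h <- 60 / bin_min
  k <- floor(length(x$counts) / (bin_min * 6))
  y <- tapply(x$counts[seq_len(k * bin_min * 6)],
              rep(seq_len(k), each = bin_min * 6), sum)
  n_days <- floor(k / (24 * per_h))
  # rows: hours 6 .. 54 relative to each day's start
  row_bins <- as.integer(48 * per_h)
  mat <- matrix(NA_real_, nrow = row_bins, ncol = max(n_days - 1, 1))
  for (d in seq_len(max(n_days - 1, 1))) {
    from <- as.integer((24 * (d - 1) + 6) * per_h) + 1L
    to <- from + row_bins - 1L
    if (to <= k) mat[, d] <- y[from:to]
  }
  graphics::image(x = seq(6, 54, length.out = row_bins),
                  y = seq_len(ncol(mat)), z = sqrt(mat),
                  col = grDevices::gray.colors(64, start = 0, end = 1,
                                               rev = TRUE),
                  xlab = "ZT (h, double-plotted 6-30)", ylab = "day",
                  ylim = c(ncol(mat) + 0.5, 0.5), ...)
  invisible(x)
}
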