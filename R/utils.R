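#' Wrap a phase difference into (-half, half]
#'
#' Circular quantities on a cycle of length `period` are mapped to the
#' half-open interval `(-period/2, period/2]` so that a delay of, say,
#' +2 h and a wrap-around value of -22 h compare equal.
#'
#' @param x numeric vector of hours (or any circular unit).
#' @param period cycle length, default 24.
#' @return numeric vector in `(-period/2, period/2]`.
#' @export
wrap_phase <- function(x, period = 24) {
  y <- x %% period
  y[y > period / 2] <- y[y > period / 2] - period
  # boundary: -period/2 maps to +period/2
  y[y == -period / 2] <- period / 2
  y
}

#' Circular mean of clock times
#'
#' @param x times in hours on a cycle of length `period`.
#' @param period cycle length in hours (default 24).
#' @return mean time in `[0, period)`, or `NA` if `x` is empty.
#' @export
circular_mean_hours <- function(x, period = 24) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  ang <- 2 * pi * x / period
  m <- atan2(mean(sin(ang)), mean(cos(ang)))
  (m * period / (2 * pi)) %% period
}

# Unwrap a daily marker sequence: each value is brought within half a cycle
# of the running median of the last few unwrapped values, so a single
# outlying marker cannot shift the rest of the series by a full cycle.
# NAs are carried through.
unwrap_series <- function(x, period = 24, ref_window = 5L) {
  out <- x
  refs <- numeric(0)
  for (i in seq_along(x)) {
    if (!is.finite(x[i])) next
    if (length(refs)) {
      ref <- stats::median(utils::tail(refs, ref_window))
      k <- round((ref - x[i]) / period)
      out[i] <- x[i] + k * period
    } else {
      out[i] <- x[i]
    }
    refs <- c(refs, out[i])
  }
  out
}

# Derive a child seed from a base seed by a fixed offset, kept within the
# 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1009 * offset) %% 2147483647)
}

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
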