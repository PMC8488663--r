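#' Build a lighting schedule
#'
#' Constructs a per-day light schedule for the four protocols used in
#' dim-light-in-the-evening (DLE) experiments:
#' \describe{
#'   \item{LD}{12:12 light/dark, 200 lx in ZT 0--12, darkness in ZT 12--24.}
#'   \item{DLE}{200 lx in ZT 0--12, 20 lx dim evening light in ZT 12--16,
#'     darkness in ZT 16--24.}
#'   \item{LD16_8}{long-day 16:8 photoperiod, 200 lx in ZT 0--16.}
#'   \item{DD}{constant darkness.}
#' }
#' Schedules from successive protocol blocks can be concatenated with
#' [c.light_schedule()], e.g. 7 d LD followed by 13 d DLE.
#'
#' @param protocol one of `"LD"`, `"DLE"`, `"LD16_8"`, `"DD"`.
#' @param n_days number of days (>= 1).
#' @return an object of class `light_schedule`: a data frame with columns
#'   `day`, `start_zt`, `end_zt`, `lux` and attributes `protocols` (per-day
#'   protocol labels) and `n_days`.
#' @examples
#' sched <- make_schedule("DLE", 1)
#' lux_at(sched, c(6, 13, 20))   # 200, 20, 0
#' @export
make_schedule <- function(protocol, n_days) {
  protocol <- match.arg(protocol, c("LD", "DLE", "LD16_8", "DD"))
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days < 1 ||
      n_days != round(n_days)) {
    stop("n_days must be a positive integer")
  }
  segs <- switch(protocol,
    LD     = data.frame(start_zt = c(0, 12), end_zt = c(12, 24),
                        lux = c(200, 0)),
    DLE    = data.frame(start_zt = c(0, 12, 16), end_zt = c(12, 16, 24),
                        lux = c(200, 20, 0)),
    LD16_8 = data.frame(start_zt = c(0, 16), end_zt = c(16, 24),
                        lux = c(200, 0)),
    DD     = data.frame(start_zt = 0, end_zt = 24, lux = 0)
  )
  days <- rep(seq_len(n_days), each = nrow(segs))
  out <- data.frame(day = days,
                    start_zt = rep(segs$start_zt, n_days),
                    end_zt = rep(segs$end_zt, n_days),
                    lux = rep(segs$lux, n_days))
  structure(out,
            class = c("light_schedule", "data.frame"),
            protocols = rep(protocol, n_days),
            n_days = as.integer(n_days))
}

#' Concatenate lighting schedules
#'
#' Appends schedules day-wise, renumbering days, so that e.g. a 7-day LD
#' baseline can be followed by a 13-day DLE block.
#'
#' @param ... `light_schedule` objects.
#' @return a `light_schedule` covering all days in order.
#' @export
c.light_schedule <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "light_schedule")))
  offset <- 0L
  rows <- list()
  protos <- character(0)
  for (p in parts) {
    q <- as.data.frame(p)
    q$day <- q$day + offset
    rows[[length(rows) + 1L]] <- q
    protos <- c(protos, attr(p, "protocols"))
    offset <- offset + attr(p, "n_days")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("light_schedule", "data.frame"),
            protocols = protos,
            n_days = offset)
}

#' Light intensity at given times
#'
#' @param schedule a `light_schedule`.
#' @param time_h absolute time in hours since the start of day 1 (ZT0); may
#'   exceed 24.
#' @return lux at each time; times beyond the schedule repeat its last day.
#' @export
lux_at <- function(schedule, time_h) {
  n_days <- attr(schedule, "n_days")
  day <- pmin(floor(time_h / 24) + 1, n_days)
  zt <- time_h %% 24
  lux <- numeric(length(time_h))
  for (d in unique(day)) {
    segs <- schedule[schedule$day == d, , drop = FALSE]
    idx <- which(day == d)
    for (k in seq_len(nrow(segs))) {
      sel <- idx[zt[idx] >= segs$start_zt[k] & zt[idx] < segs$end_zt[k]]
      lux[sel] <- segs$lux[k]
    }
  }
  lux
}

#' @export
print.light_schedule <- function(x, ...) {
  protos <- attr(x, "protocols")
  cat("Light schedule:", attr(x, "n_days"), "day(s)\n")
  r <- rle(protos)
  cat(paste(sprintf("%d d %s", r$lengths, r$values), collapse = " + "), "\n")
  invisible(x)
}
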