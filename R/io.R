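# Plain-text file contracts: CSV payloads with a JSON sidecar for the
# activity recording metadata. All CSVs are comma-separated, UTF-8, with a
# header row and '.' decimal separator.

#' Write an activity recording to CSV + JSON sidecar
#'
#' @param recording an `activity_recording`.
#' @param csv_path path of the counts CSV (`bin_start_s,count`); the sidecar
#'   is written next to it with extension `.json`.
#' @return invisibly, the sidecar path.
#' @export
write_activity_csv <- function(recording, csv_path) {
  utils::write.csv(
    data.frame(bin_start_s = (seq_along(recording$counts) - 1L) * 10L,
               count = recording$counts),
    csv_path, row.names = FALSE)
  sched <- as.data.frame(recording$schedule)
  sidecar <- list(bin_width_s = recording$bin_width_s,
                  start_zt_h = recording$start_zt,
                  schedule = lapply(split(sched, sched$day), function(d)
                    list(day = d$day[1],
                         segments = d[, c("start_zt", "end_zt", "lux")])),
                  protocols = attr(recording$schedule, "protocols"),
                  ground_truth = recording$ground_truth)
  json_path <- sub("\\.csv$", ".json", csv_path)
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(json_path)
}

#' Read an activity recording written by [write_activity_csv()]
#'
#' @param csv_path path of the counts CSV.
#' @return an `activity_recording`.
#' @export
read_activity_csv <- function(csv_path) {
  counts <- utils::read.csv(csv_path)$count
  side <- jsonlite::read_json(sub("\\.csv$", ".json", csv_path),
                              simplifyVector = TRUE)
  segs <- do.call(rbind, lapply(side$schedule, function(d) {
    s <- as.data.frame(d$segments)
    s$day <- d$day
    s
  }))
  segs <- segs[order(segs$day, segs$start_zt), c("day", "start_zt", "end_zt", "lux")]
  rownames(segs) <- NULL
  schedule <- structure(segs, class = c("light_schedule", "data.frame"),
                        protocols = side$protocols,
                        n_days = length(side$protocols))
  gt <- if (!is.null(side$ground_truth)) as.data.frame(side$ground_truth)
  structure(list(counts = as.integer(counts),
                 bin_width_s = side$bin_width_s, start_zt = side$start_zt_h,
                 schedule = schedule, ground_truth = gt, params = NULL),
            class = "activity_recording")
}

#' Write / read a bioluminescence trace CSV
#'
#' Columns `minute`, `shutter` (`open`/`closed`), `counts`.
#'
#' @param trace a `biolum_trace`.
#' @param path CSV path.
#' @export
write_biolum_csv <- function(trace, path) {
  utils::write.csv(
    data.frame(minute = trace$minute,
               shutter = ifelse(trace$shutter_open, "open", "closed"),
               counts = trace$counts),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_biolum_csv
#' @export
read_biolum_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(list(counts = d$counts, shutter_open = d$shutter == "open",
                 minute = d$minute, phi_true = NA_real_, tau_true = NA_real_),
            class = "biolum_trace")
}

#' Write / read a qPCR Ct table CSV
#'
#' Columns `sample_id,tissue,condition,zt,gene,role,ct`.
#'
#' @param table an `expression_table`.
#' @param path CSV path.
#' @export
write_qpcr_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("sample_id", "tissue",
                                            "condition", "zt", "gene",
                                            "role", "ct")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_csv
#' @export
read_qpcr_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(d, class = c("expression_table", "data.frame"))
}

#' Write / read a recognition-trials CSV
#'
#' @param dataset a `recognition_dataset`.
#' @param path CSV path.
#' @export
write_trials_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(d, class = c("recognition_dataset", "data.frame"))
}
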