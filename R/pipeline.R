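# End-to-end orchestration: simulate every modality under a named
# configuration, run each analysis stage, and collect recovered quantities
# next to the generator ground truths in one machine-readable summary.

#' Build a run configuration
#'
#' @param n_animals cohort size for the activity arms (default 12).
#' @param days_ld,days_dle baseline and treatment day counts (7 and 13).
#' @param seed master seed; all stage seeds derive from it by fixed offsets.
#' @param n_boot parametric-bootstrap iterations for the sleep-effect CI.
#' @param baseline_days,treatment_days day windows for the delay estimates
#'   (defaults: LD days 2..7 and the last 5 DLE days).
#' @return list of class `run_config`; serializable to YAML/JSON.
#' @export
run_config <- function(n_animals = 12, days_ld = 7, days_dle = 13, seed = 1,
                       n_boot = 2000, baseline_days = NULL,
                       treatment_days = NULL) {
  if (days_ld < 1 || days_dle < 1) stop("day counts must be >= 1")
  if (n_animals < 1) stop("n_animals must be >= 1")
  if (is.null(baseline_days)) baseline_days <- 2:days_ld
  if (is.null(treatment_days))
    treatment_days <- (days_ld + days_dle - 4):(days_ld + days_dle)
  structure(list(n_animals = n_animals, days_ld = days_ld,
                 days_dle = days_dle, seed = seed, n_boot = n_boot,
                 baseline_days = baseline_days,
                 treatment_days = treatment_days),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x[c("n_animals", "days_ld", "days_dle", "seed",
                          "n_boot", "baseline_days", "treatment_days")])
}

# delay estimates for the three markers of a cohort
cohort_delays <- function(recordings, baseline_days, treatment_days) {
  tabs <- lapply(recordings, phase_markers)
  sapply(c("onset_zt", "midpoint_zt", "offset_zt"), function(m)
    phase_delay(tabs, baseline_days, treatment_days, m)$mean_h)
}

#' Run the full synthetic experiment
#'
#' Simulates the wild-type DLE cohort, the constant-darkness arms, the
#' bioluminescence groups, the qPCR presets and the recognition dataset
#' under one master seed, runs every analysis stage, and returns all
#' recovered quantities with their generator ground truths.
#'
#' @param config a [run_config()].
#' @return list of class `experiment_summary` with elements `recovered`
#'   (named numeric quantities: `onset_delay_h`, `midpoint_delay_h`,
#'   `offset_delay_h`, `dd_phase_diff_h`, `free_run_tau_h`,
#'   `dbp_acrophase_delay_h`, `reverba_pooled_dphi_h`, `hmgcr_dle_peak_zt`,
#'   `r2_at_2h`, `lmm_slope`, `lmm_chi2`, `lmm_ci_low`, `lmm_ci_high`),
#'   `truth` (programmed values) and `config`.
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  # --- locomotor phase delays -------------------------------------------
  wt <- simulate_cohort("wt_dle", config$n_animals, seed = seed)
  delays <- cohort_delays(wt, config$baseline_days, config$treatment_days)

  # --- constant darkness: free run and prior-lighting offset ------------
  dd_ld <- simulate_cohort("dd_prior_ld", 8, seed = child_seed(seed, 100))
  dd_dle <- simulate_cohort("dd_prior_dle", 8, seed = child_seed(seed, 200))
  dd_diff <- dd_group_difference(dd_ld, dd_dle)
  taus <- vapply(c(dd_ld, dd_dle),
                 function(r) free_run_period(phase_markers(r)), numeric(1))

  # --- hepatic bioluminescence ------------------------------------------
  bl <- biolum_group_difference(n_per_group = 8, delta_h = 2.34,
                                seed = child_seed(seed, 300))

  # --- qPCR phase shifts -------------------------------------------------
  qt <- generate_qpcr(qpcr_preset("reverba"), seed = child_seed(seed, 400))
  shifts <- expression_phase_shifts(qt)
  pooled <- pooled_shift_test(shifts$delta_phi)
  qh <- generate_qpcr(qpcr_preset("hmgcr"), seed = child_seed(seed, 500))
  cells <- normalize_expression(qh)$cells
  dle_cells <- cells[cells$condition == "DLE", ]
  hmgcr_peak <- dle_cells$zt[which.max(dle_cells$mean_ddct)]

  # --- recognition memory ------------------------------------------------
  rec <- generate_recognition(seed = child_seed(seed, 600))
  scan <- window_scan(rec)
  lmm <- lmm_sleep_effect(rec, n_boot = config$n_boot,
                          seed = child_seed(seed, 700))

  recovered <- list(
    onset_delay_h = unname(delays["onset_zt"]),
    midpoint_delay_h = unname(delays["midpoint_zt"]),
    offset_delay_h = unname(delays["offset_zt"]),
    dd_phase_diff_h = dd_diff,
    free_run_tau_h = mean(taus, na.rm = TRUE),
    dbp_acrophase_delay_h = bl,
    reverba_pooled_dphi_h = pooled$mean,
    hmgcr_dle_peak_zt = hmgcr_peak,
    r2_at_2h = attr(scan, "r2_at_120"),
    lmm_slope = lmm$slope, lmm_chi2 = lmm$chi2,
    lmm_ci_low = lmm$ci_low, lmm_ci_high = lmm$ci_high)
  truth <- list(onset_delay_h = 3.59, midpoint_delay_h = 2.57,
                offset_delay_h = 2.52, dd_phase_diff_h = 4.0,
                free_run_tau_h = 23.7, dbp_acrophase_delay_h = 2.34,
                reverba_pooled_dphi_h = 2.07, hmgcr_dle_peak_zt = 14,
                lmm_slope = attr(rec, "truth")$beta1)
  structure(list(recovered = recovered, truth = truth, config = config),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat("Synthetic DLE experiment summary (seed ", x$config$seed, ")\n", sep = "")
  for (k in names(x$recovered)) {
    tv <- if (!is.null(x$truth[[k]])) sprintf("  [programmed %.3g]",
                                              x$truth[[k]]) else ""
    cat(sprintf("  %-24s %8.3f%s\n", k, x$recovered[[k]], tv))
  }
  invisible(x)
}

#' Write an experiment summary as JSON
#'
#' @param summary an `experiment_summary`.
#' @param path output JSON path.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(list(recovered = summary$recovered,
                            truth = summary$truth,
                            config = unclass(summary$config)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pooled marker difference between two constant-darkness groups
#'
#' Mean over the three phase markers of the between-group difference of
#' per-animal marker means (markers unwrapped per animal over the DD days).
#'
#' @param group_ld,group_dle lists of `activity_recording` under DD.
#' @return difference in hours (group_dle minus group_ld).
#' @export
dd_group_difference <- function(group_ld, group_dle) {
  marker_mean <- function(rec, marker) {
    tab <- phase_markers(rec)
    mean(unwrap_series(tab[[marker]]), na.rm = TRUE)
  }
  diffs <- vapply(c("onset_zt", "midpoint_zt", "offset_zt"), function(m) {
    a <- vapply(group_ld, marker_mean, numeric(1), marker = m)
    b <- vapply(group_dle, marker_mean, numeric(1), marker = m)
    mean(b, na.rm = TRUE) - mean(a, na.rm = TRUE)
  }, numeric(1))
  mean(diffs)
}

#' Between-group bioluminescence acrophase difference
#'
#' Simulates two groups of shutter-gated traces whose true acrophases differ
#' by `delta_h`, runs background correction, circadian-band detrending and
#' per-cycle acrophase estimation, and returns the recovered group
#' difference on the circular scale.
#'
#' @param n_per_group traces per group (default 8).
#' @param delta_h programmed acrophase offset in hours (default 2.34).
#' @param phi_base acrophase of the first group (default 10 h).
#' @param days trace length in days (default 5).
#' @param seed integer seed.
#' @return recovered difference in hours, wrapped to `(-12, 12]`.
#' @export
biolum_group_difference <- function(n_per_group = 8, delta_h = 2.34,
                                    phi_base = 10, days = 5, seed = 1) {
  est <- function(phi, k) {
    tr <- generate_bioluminescence(phi, tau_true = 23.7, days = days,
                                   seed = child_seed(seed, k))
    acrophase(dwt_detrend(background_correct(tr)))$phi_h
  }
  phi_ld <- vapply(seq_len(n_per_group), function(i) est(phi_base, i),
                   numeric(1))
  phi_dle <- vapply(seq_len(n_per_group), function(i)
    est(phi_base + delta_h, 1000 + i), numeric(1))
  wrap_phase(circular_mean_hours(phi_dle) - circular_mean_hours(phi_ld), 24)
}
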