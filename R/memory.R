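# Sleep-history window scan and mixed-effects inference for recognition
# memory. The scan regresses the 8 trial-type cell means of the recognition
# ratio on cell means of prior-sleep proportion over window widths of 10-180
# min; the mixed model tests the fixed effect of preceding 2-h sleep with a
# per-mouse random intercept, a likelihood-ratio test and a parametric
# bootstrap CI.

#' Recognition ratio for one test segment
#'
#' @param novel_s,familiar_s exploration times (s) of the novel and familiar
#'   stimulus in the segment.
#' @return `novel / (novel + familiar)`, `NA` when total exploration is 0.
#' @export
recognition_ratio <- function(novel_s, familiar_s) {
  tot <- novel_s + familiar_s
  out <- ifelse(tot > 0, novel_s / tot, NA_real_)
  if (any(!is.finite(out)))
    warning(sum(!is.finite(out)), " trial(s) with zero exploration undefined")
  out
}

# Per-trial analysis table: ratio for a segment plus prior sleep at a width.
trial_table <- function(dataset, sleep = attr(dataset, "sleep"),
                        segment = "0_60", width_h = 2) {
  nv <- dataset[[paste0("novel_", segment)]]
  fm <- dataset[[paste0("familiar_", segment)]]
  data.frame(mouse_id = dataset$mouse_id, condition = dataset$condition,
             zt = dataset$zt, stimulus = dataset$stimulus,
             ratio = recognition_ratio(nv, fm),
             sleep = vapply(seq_len(nrow(dataset)), function(i)
               prior_sleep(sleep[[dataset$mouse_id[i]]],
                           dataset$trial_start_h[i], width_h), numeric(1)),
             sample_exploration_s = dataset$sample_exploration_s)
}

#' Sliding-window sleep-history scan
#'
#' For each window width, computes the sleep proportion preceding every
#' trial, averages ratio and sleep within the 8 lighting x ZT x stimulus
#' cells, fits ordinary least squares of mean ratio on mean sleep across
#' cells, and records the coefficient of determination. A quadratic trend
#' of R-squared on width and a plateau summary (R-squared at 120 min;
#' smallest width reaching 95 percent of the maximum) are attached.
#'
#' @param dataset a `recognition_dataset`.
#' @param sleep list of per-mouse `sleep_series` (defaults to the attribute
#'   carried by the generated dataset).
#' @param widths_min window widths in minutes (default `seq(10, 180, 10)`).
#' @param segment test segment, default first 60 s.
#' @return object of class `window_scan`: data frame `width_min`, `r2`, with
#'   attributes `quadratic` (coefficients of `r2 ~ width + width^2`),
#'   `r2_at_120`, `plateau_width_min`, and `cells_at_120` (the 8 cell means
#'   at the 2-h width).
#' @export
window_scan <- function(dataset, sleep = attr(dataset, "sleep"),
                        widths_min = seq(10, 180, by = 10),
                        segment = "0_60") {
  res <- data.frame(width_min = widths_min, r2 = NA_real_)
  cells120 <- NULL
  for (k in seq_along(widths_min)) {
    tt <- trial_table(dataset, sleep, segment, widths_min[k] / 60)
    tt <- tt[is.finite(tt$ratio) & is.finite(tt$sleep), ]
    cell <- stats::aggregate(cbind(ratio, sleep) ~ condition + zt + stimulus,
                             data = tt, FUN = mean)
    if (nrow(cell) < 2) next
    fit <- stats::lm(ratio ~ sleep, data = cell)
    tss <- sum((cell$ratio - mean(cell$ratio))^2)
    res$r2[k] <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss
                 else NA_real_
    if (widths_min[k] == 120) cells120 <- cell
  }
  w <- res$width_min
  quad <- stats::coef(stats::lm(res$r2 ~ w + I(w^2)))
  r2max <- max(res$r2, na.rm = TRUE)
  plateau <- res$width_min[which(res$r2 >= 0.95 * r2max)[1]]
  structure(res, class = c("window_scan", "data.frame"),
            quadratic = quad,
            r2_at_120 = res$r2[res$width_min == 120],
            plateau_width_min = plateau, cells_at_120 = cells120)
}

#' @export
print.window_scan <- function(x, ...) {
  cat("Sleep-history window scan:", nrow(x), "widths\n")
  cat(sprintf("R2 at 120 min: %.3f; 95%% plateau reached at %d min\n",
              attr(x, "r2_at_120"), attr(x, "plateau_width_min")))
  invisible(as.data.frame(x))
}

#' Plot a window-scan curve
#'
#' @param x a `window_scan`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.window_scan <- function(x, ...) {
  graphics::plot(x$width_min, x$r2, type = "b", pch = 19,
                 xlab = "window width (min)",
                 ylab = expression(R^2), ylim = c(0, 1), ...)
  q <- attr(x, "quadratic")
  graphics::curve(q[1] + q[2] * x + q[3] * x^2, add = TRUE, lty = 2)
  invisible(x)
}

# random-intercept ML fit with LR test of one fixed effect
lmm_lr <- function(df, response, predictor, n_boot = 0, seed = NULL) {
  df <- df[is.finite(df[[response]]) & is.finite(df[[predictor]]), ]
  full_f <- stats::as.formula(paste(response, "~", predictor, "+ (1 | mouse_id)"))
  null_f <- stats::as.formula(paste(response, "~ 1 + (1 | mouse_id)"))
  fallback <- FALSE
  # singular random-effect fits are legitimate under null couplings; lme4's
  # boundary message is informational only
  full <- tryCatch(suppressMessages(lme4::lmer(full_f, data = df,
                                               REML = FALSE)),
                   error = function(e) NULL)
  null <- tryCatch(suppressMessages(lme4::lmer(null_f, data = df,
                                               REML = FALSE)),
                   error = function(e) NULL)
  if (is.null(full) || is.null(null)) {
    # degenerate random effects: ordinary regression fallback
    fallback <- TRUE
    full <- stats::lm(stats::as.formula(paste(response, "~", predictor)),
                      data = df)
    null <- stats::lm(stats::as.formula(paste(response, "~ 1")), data = df)
  }
  dev_full <- -2 * as.numeric(stats::logLik(full))
  dev_null <- -2 * as.numeric(stats::logLik(null))
  chi2 <- max(dev_null - dev_full, 0)
  slope <- if (fallback) unname(stats::coef(full)[2])
           else unname(lme4::fixef(full)[2])
  ci <- c(NA_real_, NA_real_)
  boot_slopes <- NULL
  if (n_boot > 0 && !fallback) {
    sims <- stats::simulate(full, nsim = n_boot, seed = seed)
    boot_slopes <- vapply(sims, function(y) {
      tryCatch(suppressMessages(unname(lme4::fixef(lme4::refit(full, y))[2])),
               error = function(e) NA_real_)
    }, numeric(1))
    boot_slopes <- boot_slopes[is.finite(boot_slopes)]
    ci <- unname(stats::quantile(boot_slopes, c(0.025, 0.975)))
  }
  structure(list(slope = slope, chi2 = chi2,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
                 fit = full, fallback_lm = fallback,
                 response = response, predictor = predictor,
                 n = nrow(df)),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("Mixed model %s ~ %s + (1 | mouse): slope = %.3f, LR chi2(1) = %.2f, p = %.4g\n",
              x$response, x$predictor, x$slope, x$chi2, x$p))
  if (is.finite(x$ci_low))
    cat(sprintf("Parametric-bootstrap 95%% CI (%d iterations): [%.3f, %.3f]\n",
                x$n_boot, x$ci_low, x$ci_high))
  if (x$fallback_lm)
    cat("Note: singular random-effect fit; ordinary regression used.\n")
  invisible(x)
}

#' Mixed-effects test of the preceding-2-h sleep effect
#'
#' Fits `ratio ~ sleep2h + (1 | mouse)` by maximum likelihood, compares its
#' deviance with the null model without the fixed effect (likelihood-ratio
#' chi-squared, 1 df), and computes a percentile parametric-bootstrap
#' confidence interval of the slope by simulating from the fitted full
#' model and refitting.
#'
#' @param dataset a `recognition_dataset`.
#' @param sleep list of per-mouse `sleep_series`.
#' @param n_boot bootstrap iterations (default 2000; 10000 reproduces the
#'   full-length analysis).
#' @param seed seed for the bootstrap simulation.
#' @param segment test segment (default first 60 s).
#' @return an `lmm_result`: `slope`, `chi2`, `p`, `ci_low`, `ci_high`.
#' @export
lmm_sleep_effect <- function(dataset, sleep = attr(dataset, "sleep"),
                             n_boot = 2000, seed = 1, segment = "0_60") {
  tt <- trial_table(dataset, sleep, segment, 2)
  lmm_lr(tt, "ratio", "sleep", n_boot = n_boot, seed = seed)
}

#' Control analyses: exploration versus sleep
#'
#' Two mixed models probing confounds: (1) sample-phase exploration time on
#' preceding-2-h sleep (should be null when exploration is independent of
#' sleep history) and (2) recognition ratio on sample exploration.
#'
#' @inheritParams lmm_sleep_effect
#' @return list with `sleep_to_exploration` and `exploration_to_ratio`,
#'   both `lmm_result` objects (no bootstrap).
#' @export
exploration_effects <- function(dataset, sleep = attr(dataset, "sleep"),
                                segment = "0_60") {
  tt <- trial_table(dataset, sleep, segment, 2)
  list(sleep_to_exploration =
         lmm_lr(tt, "sample_exploration_s", "sleep"),
       exploration_to_ratio =
         lmm_lr(tt, "ratio", "sample_exploration_s"))
}
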