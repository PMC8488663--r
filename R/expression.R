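# Relative-expression normalization and acrophase estimation for qPCR
# rhythm tables: 2^-dCt against the geometric mean of two housekeeping
# genes, peak normalization to 2^-ddCt within each lighting condition,
# single-harmonic (24-h cosinor) acrophase with a center-of-gravity
# cross-check, and pooled phase-shift tests.

#' Normalize a qPCR Ct table
#'
#' Per sample, `dCt = Ct(target) - mean(Ct(housekeeping))`; the relative
#' level is `2^-dCt` (equivalently the ratio of `2^-Ct` to the geometric
#' mean of the housekeeping `2^-Ct`, computed on the Ct scale to avoid
#' underflow). Within each tissue x gene x condition, sample values are then
#' divided by the highest ZT mean, giving `2^-ddCt` with per-condition
#' maximum mean exactly 1.
#'
#' @param table an `expression_table` (long format: `sample_id`, `tissue`,
#'   `condition`, `zt`, `gene`, `role`, `ct`).
#' @return list of class `normalized_expression`: `samples` (per-sample
#'   `rel` = 2^-dCt and `ddct` = 2^-ddCt) and `cells` (per tissue x gene x
#'   condition x ZT mean `mean_ddct` and replicate count `n`).
#' @export
normalize_expression <- function(table) {
  tgt <- table[table$role == "target", , drop = FALSE]
  hk <- table[table$role == "housekeeping", , drop = FALSE]
  hk_mean <- tapply(hk$ct, hk$sample_id, mean)
  hk_n <- tapply(hk$ct, hk$sample_id, length)
  bad <- names(hk_n)[hk_n < 2]
  if (length(bad)) {
    warning(length(bad), " sample(s) without both housekeeping Cts dropped")
    tgt <- tgt[!(tgt$sample_id %in% bad), , drop = FALSE]
  }
  tgt$rel <- 2^-(tgt$ct - as.numeric(hk_mean[tgt$sample_id]))
  tgt$ddct <- NA_real_
  cells <- list()
  for (key in split(seq_len(nrow(tgt)),
                    interaction(tgt$tissue, tgt$gene, tgt$condition,
                                drop = TRUE))) {
    sub <- tgt[key, ]
    zt_mean <- tapply(sub$rel, sub$zt, mean)
    peak <- max(zt_mean)
    tgt$ddct[key] <- sub$rel / peak
    cells[[length(cells) + 1L]] <- data.frame(
      tissue = sub$tissue[1], gene = sub$gene[1], condition = sub$condition[1],
      zt = as.numeric(names(zt_mean)),
      mean_ddct = as.numeric(zt_mean) / peak,
      n = as.integer(base::table(sub$zt)))
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  structure(list(samples = tgt, cells = cells),
            class = "normalized_expression")
}

#' Cosinor acrophase with center-of-gravity cross-check
#'
#' Fits `y = m + a cos(2 pi (ZT - phi) / 24)` by least squares (period fixed
#' at 24 h) to a mean expression profile. The acrophase is the fitted peak
#' time; the center of gravity (circular mean of ZT angles weighted by the
#' positive part of the fitted wave above the mesor) is also reported, and
#' equals the fitted acrophase for a single-harmonic fit on an equispaced
#' grid. A rhythm is flagged unreliable when the zero-amplitude F test is
#' not even suggestive (p > 0.3).
#'
#' @param zt sampled Zeitgeber times (>= 3 distinct values).
#' @param y mean expression at each `zt`.
#' @return list of class `acrophase_fit`: `phi_h`, `cog_h`, `mesor`,
#'   `amplitude`, `r_squared`, `f_p`, `reliable`.
#' @export
cog_acrophase <- function(zt, y) {
  keep <- is.finite(y)
  zt <- zt[keep]; y <- y[keep]
  if (length(unique(zt)) < 3) stop("need at least 3 distinct ZT points")
  ang <- 2 * pi * zt / 24
  fit <- stats::lm(y ~ cos(ang) + sin(ang))
  bc <- stats::coef(fit)[2]
  bs <- stats::coef(fit)[3]
  phi <- (atan2(bs, bc) * 24 / (2 * pi)) %% 24
  amp <- sqrt(bc^2 + bs^2)
  m <- stats::coef(fit)[1]
  # center of gravity of the fitted wave over a fine grid
  grid <- seq(0, 24 - 0.05, by = 0.05)
  w <- pmax(m + amp * cos(2 * pi * (grid - phi) / 24) - m, 0)
  cog <- if (sum(w) > 0) {
    a <- 2 * pi * grid / 24
    (atan2(sum(w * sin(a)), sum(w * cos(a))) * 24 / (2 * pi)) %% 24
  } else NA_real_
  f_p <- if (length(y) > 3) {
    a0 <- stats::anova(stats::lm(y ~ 1), fit)
    a0$`Pr(>F)`[2]
  } else NA_real_
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  structure(list(phi_h = unname(phi), cog_h = cog, mesor = unname(m),
                 amplitude = unname(amp),
                 r_squared = r2, f_p = f_p,
                 reliable = is.na(f_p) || f_p <= 0.3),
            class = "acrophase_fit")
}

#' @export
print.acrophase_fit <- function(x, ...) {
  cat(sprintf("Acrophase %.2f h (CoG %.2f h), mesor %.3g, amplitude %.3g%s\n",
              x$phi_h, x$cog_h, x$mesor, x$amplitude,
              if (!x$reliable) " [unreliable: no detectable rhythm]" else ""))
  invisible(x)
}

#' Phase shift between two acrophases
#'
#' @param phi_ld,phi_dle acrophases in hours.
#' @return `phi_dle - phi_ld` wrapped into `(-12, 12]`.
#' @examples
#' phase_shift(14, 16)  #  +2
#' phase_shift(23, 1)   #  +2 across midnight
#' phase_shift(2, 23)   #  -3
#' @export
phase_shift <- function(phi_ld, phi_dle) {
  if (!is.finite(phi_ld) || !is.finite(phi_dle)) return(NA_real_)
  wrap_phase(phi_dle - phi_ld, 24)
}

#' Pooled one-sample test of phase shifts
#'
#' Tests whether the mean phase shift across tissues differs from zero by a
#' two-tailed one-sample Student t test.
#'
#' @param dphi numeric vector of per-tissue phase shifts (n >= 2).
#' @return list: `mean`, `sem`, `t`, `df`, `p`, `degenerate` (TRUE when the
#'   shifts have zero spread).
#' @export
pooled_shift_test <- function(dphi) {
  dphi <- dphi[is.finite(dphi)]
  if (length(dphi) < 2) stop("need at least 2 phase-shift values")
  s <- stats::sd(dphi)
  if (s == 0) {
    return(list(mean = mean(dphi), sem = 0, t = NA_real_,
                df = length(dphi) - 1L, p = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(dphi, mu = 0)
  list(mean = mean(dphi), sem = s / sqrt(length(dphi)),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Per tissue x gene phase-shift table from a qPCR table
#'
#' Normalizes, fits acrophases per tissue x gene x condition, and returns
#' wrapped shifts `phi_DLE - phi_LD` with reliability flags.
#'
#' @param table an `expression_table` with both LD and DLE conditions.
#' @return data frame: `tissue`, `gene`, `phi_ld`, `phi_dle`, `delta_phi`,
#'   `flag` (TRUE when either acrophase is unreliable).
#' @export
expression_phase_shifts <- function(table) {
  ne <- normalize_expression(table)
  cells <- ne$cells
  combos <- unique(cells[, c("tissue", "gene")])
  out <- NULL
  for (i in seq_len(nrow(combos))) {
    sub <- cells[cells$tissue == combos$tissue[i] &
                 cells$gene == combos$gene[i], ]
    fits <- lapply(c("LD", "DLE"), function(cond) {
      s <- sub[sub$condition == cond, ]
      if (!nrow(s)) return(NULL)
      cog_acrophase(s$zt, s$mean_ddct)
    })
    if (any(vapply(fits, is.null, logical(1)))) next
    out <- rbind(out, data.frame(
      tissue = combos$tissue[i], gene = combos$gene[i],
      phi_ld = fits[[1]]$phi_h, phi_dle = fits[[2]]$phi_h,
      delta_phi = phase_shift(fits[[1]]$phi_h, fits[[2]]$phi_h),
      flag = !(fits[[1]]$reliable && fits[[2]]$reliable)))
  }
  out
}
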