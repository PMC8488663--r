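# Synthetic qPCR threshold-cycle (Ct) tables.
#
# Target-gene expression follows a 24-h cosine (mesor + amplitude, acrophase
# phi per tissue x gene x condition); Ct values are generated on the log2
# scale (one cycle = one doubling) with Gaussian noise, and every sample
# carries Ct values for two housekeeping genes.

#' Ground-truth rhythm table for the qPCR generator
#'
#' @param tissues character vector of tissue names.
#' @param gene target gene name.
#' @param phi_ld,phi_dle acrophases (h) per tissue under LD and DLE;
#'   recycled to `length(tissues)`.
#' @param mesor,amplitude cosine mesor and amplitude on the linear
#'   expression scale (`amplitude < mesor` so expression stays positive).
#' @return data frame with one row per tissue x condition.
#' @export
qpcr_truth <- function(tissues = c("heart", "liver", "adrenal", "dhpc"),
                       gene = "gene1", phi_ld = 8, phi_dle = 10,
                       mesor = 1, amplitude = 0.8) {
  k <- length(tissues)
  rbind(
    data.frame(tissue = tissues, gene = gene, condition = "LD",
               mesor = mesor, amplitude = amplitude,
               phi = rep_len(phi_ld, k)),
    data.frame(tissue = tissues, gene = gene, condition = "DLE",
               mesor = mesor, amplitude = amplitude,
               phi = rep_len(phi_dle, k))
  )
}

#' Generate a synthetic qPCR Ct table
#'
#' Target Ct is `c0 - log2(mesor + amplitude * cos(2 pi (ZT - phi) / 24))`
#' plus Gaussian noise; housekeeping Ct values are constant plus the same
#' noise. Samples are taken at ZT 2, 8, 14 and 20.
#'
#' @param truth a data frame as returned by [qpcr_truth()] (one row per
#'   tissue x gene x condition with `mesor`, `amplitude`, `phi`).
#' @param n_rep replicates per tissue x condition x ZT cell; either a single
#'   number (default 4) or a function `(tissue, condition, zt) -> n`
#'   allowing 2-3 to mimic missing cells.
#' @param noise_sd_ct Ct noise SD (>= 0), default 0.15.
#' @param c0 target-gene Ct at unit expression (default 22).
#' @param hk_ct constant Ct values of the two housekeeping genes
#'   (default `c(Tbp = 24, Gapdh = 18)`).
#' @param zts sampled Zeitgeber times (default `c(2, 8, 14, 20)`).
#' @param seed integer seed.
#' @return data frame of class `expression_table` with columns `sample_id`,
#'   `tissue`, `condition`, `zt`, `gene`, `role` (`"target"` or
#'   `"housekeeping"`), `ct`; the ground truth is attached as attribute
#'   `truth`.
#' @export
generate_qpcr <- function(truth, n_rep = 4, noise_sd_ct = 0.15, c0 = 22,
                          hk_ct = c(Tbp = 24, Gapdh = 18),
                          zts = c(2, 8, 14, 20), seed = NULL) {
  if (noise_sd_ct < 0) stop("noise_sd_ct must be >= 0")
  if (any(truth$amplitude > truth$mesor))
    stop("amplitude > mesor: expression would be non-positive at trough")
  nrep_fun <- if (is.function(n_rep)) n_rep else function(...) n_rep
  rows <- list()
  sid <- 0L
  with_seed(seed, {
    for (r in seq_len(nrow(truth))) {
      for (zt in zts) {
        k <- nrep_fun(truth$tissue[r], truth$condition[r], zt)
        for (rep_i in seq_len(k)) {
          sid <- sid + 1L
          expr <- truth$mesor[r] +
            truth$amplitude[r] * cos(2 * pi * (zt - truth$phi[r]) / 24)
          ct_t <- c0 - log2(expr) + stats::rnorm(1, 0, noise_sd_ct)
          id <- sprintf("s%04d", sid)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = id, tissue = truth$tissue[r],
            condition = truth$condition[r], zt = zt,
            gene = c(truth$gene[r], names(hk_ct)),
            role = c("target", "housekeeping", "housekeeping"),
            ct = c(ct_t, hk_ct + stats::rnorm(2, 0, noise_sd_ct)))
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("expression_table", "data.frame"), truth = truth)
}

#' Preset qPCR ground truths
#'
#' `"reverba"`: a clock-output gene peaking at ZT8 under LD with per-tissue
#' DLE delays averaging 2.07 h across the four tissues. `"hmgcr"`: the liver
#' cholesterol-synthesis gene peaking at ZT8 under LD and ZT14 under DLE.
#'
#' @param preset `"reverba"` or `"hmgcr"`.
#' @return data frame usable as `truth` in [generate_qpcr()].
#' @export
qpcr_preset <- function(preset = c("reverba", "hmgcr")) {
  preset <- match.arg(preset)
  switch(preset,
    reverba = {
      shifts <- c(heart = 1.25, liver = 1.75, adrenal = 2.35, dhpc = 2.93)
      qpcr_truth(tissues = names(shifts), gene = "Rev-erba",
                 phi_ld = 8, phi_dle = 8 + unname(shifts))
    },
    hmgcr = qpcr_truth(tissues = "liver", gene = "Hmgcr",
                       phi_ld = 8, phi_dle = 14)
  )
}
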