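test_that("normalization reproduces hand-computed dCt arithmetic", {
  tab <- data.frame(
    sample_id = rep("s1", 3), tissue = "liver", condition = "LD",
    zt = 2, gene = c("g", "hk1", "hk2"),
    role = c("target", "housekeeping", "housekeeping"),
    ct = c(20, 18, 22))
  class(tab) <- c("expression_table", "data.frame")
  ne <- normalize_expression(tab)
  # dCt = 20 - mean(18, 22) = 0 so 2^-dCt = 1
  expect_equal(ne$samples$rel, 1)
  # uniform +1 Ct shift of the whole sample leaves the ratio unchanged
  tab2 <- tab; tab2$ct <- tab2$ct + 1
  expect_equal(normalize_expression(tab2)$samples$rel, 1)
})

test_that("per-condition peak normalization makes the max mean exactly 1", {
  tab <- generate_qpcr(qpcr_preset("reverba"), seed = 1)
  ne <- normalize_expression(tab)
  peak <- tapply(ne$cells$mean_ddct,
                 interaction(ne$cells$tissue, ne$cells$condition,
                             ne$cells$gene, drop = TRUE), max)
  expect_equal(unname(as.numeric(peak)), rep(1, length(peak)))
  expect_true(all(ne$cells$mean_ddct > 0 & ne$cells$mean_ddct <= 1))
})

test_that("reduced replicate cells still normalize", {
  nrep <- function(tissue, condition, zt)
    if (tissue == "liver" && condition == "LD" && zt == 20) 2 else 4
  tab <- generate_qpcr(qpcr_preset("hmgcr"), n_rep = nrep, seed = 2)
  ne <- normalize_expression(tab)
  cell <- ne$cells[ne$cells$condition == "LD" & ne$cells$zt == 20, ]
  expect_equal(cell$n, 2L)
  expect_true(is.finite(cell$mean_ddct))
})

test_that("samples lacking a housekeeping Ct are dropped with a warning", {
  tab <- generate_qpcr(qpcr_preset("hmgcr"), seed = 3)
  tab <- tab[!(tab$sample_id == "s0001" & tab$gene == "Tbp"), ]
  expect_warning(ne <- normalize_expression(tab), "housekeeping")
  expect_false("s0001" %in% ne$samples$sample_id)
})

test_that("cosinor acrophase is exact for noiseless sampled cosines", {
  zts <- c(2, 8, 14, 20)
  for (phi in c(8, 14, 3.5)) {
    y <- 1 + 0.8 * cos(2 * pi * (zts - phi) / 24)
    fit <- cog_acrophase(zts, y)
    expect_equal(fit$phi_h, phi, tolerance = 1e-9)
    expect_equal(fit$cog_h, phi, tolerance = 0.03)  # CoG on a 0.05-h grid
    expect_equal(fit$amplitude, 0.8, tolerance = 1e-9)
    expect_equal(fit$mesor, 1, tolerance = 1e-9)
  }
  expect_error(cog_acrophase(c(2, 2, 2), c(1, 1, 1)), "3 distinct")
})

test_that("flat profiles are flagged unreliable", {
  set.seed(4)
  fit <- cog_acrophase(c(2, 8, 14, 20), 1 + rnorm(4, 0, 0.001))
  expect_false(fit$reliable)
})

test_that("phase shifts wrap into (-12, 12] and are antisymmetric", {
  expect_equal(phase_shift(14, 16), 2)
  expect_equal(phase_shift(23, 1), 2)
  expect_equal(phase_shift(2, 23), -3)
  for (a in c(0.3, 5, 11, 17.2)) for (b in c(1.4, 9, 20)) {
    expect_equal(phase_shift(a, b), -phase_shift(b, a), tolerance = 1e-12)
    expect_lte(abs(phase_shift(a, b)), 12)
  }
})

test_that("pooled shift test matches hand-computed t statistics", {
  res <- pooled_shift_test(c(2, 3, 1, 2))
  expect_equal(res$mean, 2)
  expect_equal(res$sem, sd(c(2, 3, 1, 2)) / 2, tolerance = 1e-12)
  expect_equal(res$t, 2 / (sd(c(2, 3, 1, 2)) / 2), tolerance = 1e-9)
  expect_equal(res$df, 3)
  expect_equal(res$p, 2 * pt(-abs(res$t), 3), tolerance = 1e-12)
  deg <- pooled_shift_test(c(1, 1, 1, 1))
  expect_true(deg$degenerate)
  expect_error(pooled_shift_test(2))
})

test_that("a uniform programmed shift is recovered by the full chain", {
  tru <- qpcr_truth(gene = "g", phi_ld = 8, phi_dle = 10)  # +2 h everywhere
  tab <- generate_qpcr(tru, seed = 5)
  sh <- expression_phase_shifts(tab)
  expect_equal(nrow(sh), 4)
  expect_equal(mean(sh$delta_phi), 2, tolerance = 0.3)
})

test_that("noiseless generation round-trips acrophases at the ZT resolution", {
  tru <- qpcr_truth(tissues = "liver", gene = "g", phi_ld = 14,
                    phi_dle = 14)
  tab <- generate_qpcr(tru, noise_sd_ct = 0, seed = 6)
  sh <- expression_phase_shifts(tab)
  expect_equal(sh$phi_ld, 14, tolerance = 1e-6)
  expect_equal(sh$delta_phi, 0, tolerance = 1e-6)
})

test_that("acrophase error grows with Ct noise", {
  rmse_at <- function(noise) {
    errs <- vapply(1:6, function(s) {
      tab <- generate_qpcr(qpcr_truth(tissues = "liver", gene = "g",
                                      phi_ld = 8, phi_dle = 8),
                           noise_sd_ct = noise, seed = 600 + s)
      sh <- expression_phase_shifts(tab)
      sh$phi_ld - 8
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  expect_lt(rmse_at(0.05), rmse_at(0.8))
})
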