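test_that("background subtraction follows the printed formula with clamping", {
  panel <- make_test_panel(n_genes = 8, n_hk = 6)
  counts <- matrix(c(1000L, 5L, rep(100L, 6)), nrow = 8, ncol = 2,
                   dimnames = list(panel$genes, c("S1", "S2")))
  ntc <- stats::setNames(c(20, 10, rep(0, 6)), panel$genes)
  cm <- count_matrix(counts, ntc)
  bg <- subtract_background(cm)
  expect_equal(bg["G01", "S1"], 980)      # 1000 - 20
  expect_equal(bg["G02", "S1"], 0)        # 5 - 10 clamped
  expect_true(all(bg >= 0))

  # NTC all zero leaves counts unchanged
  cm0 <- count_matrix(counts, stats::setNames(rep(0, 8), panel$genes))
  expect_equal(subtract_background(cm0), counts + 0)
})

test_that("HK ratios divide absolute counts by the baseline profile", {
  genes <- sprintf("HK%d", 1:6)
  cat6 <- stats::setNames(rep("housekeeping", 6), genes)
  panel <- panel_definition(genes, cat6, genes,
                            stats::setNames(rep(750, 6), genes))
  counts <- matrix(1500L, 6, 1, dimnames = list(genes, "S1"))
  cm <- count_matrix(counts, stats::setNames(rep(0, 6), genes))
  expect_equal(unname(hk_ratios(cm, panel)[, 1]), rep(2, 6))

  # counts equal to baselines give ratios of exactly 1
  counts[] <- 750L
  cm <- count_matrix(counts, stats::setNames(rep(0, 6), genes))
  expect_equal(unname(hk_ratios(cm, panel)[, 1]), rep(1, 6))

  # random draw matches an independent elementwise division
  panel2 <- make_test_panel()
  cm2 <- make_test_counts(panel2, n_samples = 3, seed = 21)
  r <- hk_ratios(cm2, panel2)
  for (s in colnames(r)) {
    for (g in panel2$hk_genes) {
      expect_identical(r[g, s], cm2$counts[g, s] / panel2$hk_baseline_rpm[[g]])
    }
  }
})

test_that("normalization reproduces worked examples and the brute-force oracle", {
  # all HK ratios 0.5 and background-subtracted count 100 -> nRPM 200
  genes <- c("T1", sprintf("HK%d", 1:6))
  category <- stats::setNames(c("tumor marker", rep("housekeeping", 6)), genes)
  hk <- genes[-1]
  panel <- panel_definition(genes, category, hk,
                            stats::setNames(rep(200, 6), hk))
  counts <- matrix(c(110L, rep(100L, 6)), 7, 1, dimnames = list(genes, "S1"))
  ntc <- stats::setNames(c(10, rep(0, 6)), genes)
  nm <- normalize_counts(count_matrix(counts, ntc), panel)
  expect_equal(unname(nm$norm_ratio), 0.5)
  expect_equal(nm$nrpm["T1", "S1"], 200)

  # sample matching the baseline profile (all HK ratios 1): nRPM equals
  # the background-subtracted counts
  counts2 <- matrix(c(110L, rep(200L, 6)), 7, 1, dimnames = list(genes, "S1"))
  nm2 <- normalize_counts(count_matrix(counts2, ntc), panel)
  expect_equal(nm2$nrpm["T1", "S1"], 100)

  # random matrices match the independent reimplementation exactly
  panel3 <- make_test_panel()
  for (seed in 1:5) {
    cm <- make_test_counts(panel3, n_samples = 5, seed = seed)
    nm3 <- normalize_counts(cm, panel3)
    oracle <- oracle_nrpm(cm$counts, cm$ntc, panel3$hk_genes,
                          panel3$hk_baseline_rpm)
    expect_identical(nm3$nrpm, oracle)
  }
})

test_that("normalization invariants: norm ratio is the HK median and QC failures drop", {
  panel <- make_test_panel()
  cm <- make_test_counts(panel, n_samples = 6, seed = 9)
  nm <- normalize_counts(cm, panel)
  expect_equal(nm$norm_ratio, apply(nm$hk_ratios, 2, stats::median))
  expect_true(all(nm$nrpm >= 0))

  verdicts <- data.frame(sample_id = cm$sample_ids,
                         pass = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
                         reasons = "")
  nm2 <- normalize_counts(cm, panel, verdicts)
  expect_identical(colnames(nm2$nrpm), cm$sample_ids[verdicts$pass])

  # all-zero HK readout: normalization ratio 0, sample excluded with warning
  counts <- cm$counts
  counts[panel$hk_genes, 1] <- 0L
  cmz <- count_matrix(counts, cm$ntc)
  expect_warning(nmz <- normalize_counts(cmz, panel), "excluded")
  expect_false(cm$sample_ids[1] %in% colnames(nmz$nrpm))
})

test_that("nRPM is depth-equivariant and monotone in the raw count", {
  panel <- make_test_panel()
  cm0 <- make_test_counts(panel, n_samples = 4, seed = 13,
                          ntc_rate = 0)  # NTC fixed at zero for equivariance
  cm <- count_matrix(cm0$counts * 2L, cm0$ntc)  # even counts: 0.5x stays integral
  nm <- normalize_counts(cm, panel)
  for (c_scale in c(0.5, 2, 10)) {
    counts2 <- cm$counts
    counts2[, 2] <- counts2[, 2] * c_scale
    nm2 <- normalize_counts(count_matrix(counts2, cm$ntc), panel)
    expect_equal(nm2$nrpm[, 2], nm$nrpm[, 2], tolerance = 1e-12)
    expect_equal(nm2$nrpm[, -2], nm$nrpm[, -2], tolerance = 1e-15)
  }

  # monotone in the raw count of the gene, HK counts fixed
  counts3 <- cm$counts
  counts3["G01", 1] <- counts3["G01", 1] + 500L
  nm3 <- normalize_counts(count_matrix(counts3, cm$ntc), panel)
  expect_gt(nm3$nrpm["G01", 1], nm$nrpm["G01", 1])
  expect_equal(nm3$nrpm[-1, 1], nm$nrpm[-1, 1])
})

test_that("the normalization ratio is robust to a minority of corrupted HK ratios", {
  panel <- make_test_panel(n_genes = 20, n_hk = 7)
  cm <- make_test_counts(panel, n_samples = 1, seed = 31)
  base <- hk_ratios(cm, panel)[, 1]
  # perturb fewer than half (3 of 7) of the HK counts wildly
  counts2 <- cm$counts
  counts2[panel$hk_genes[1:3], 1] <- counts2[panel$hk_genes[1:3], 1] * 100L
  nm2 <- normalize_counts(count_matrix(counts2, cm$ntc), panel)
  expect_gte(nm2$norm_ratio[[1]], min(base))
  expect_lte(nm2$norm_ratio[[1]], max(base))
})
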