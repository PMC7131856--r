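test_that("simulated panel has the configured structure and is seed-deterministic", {
  cfg <- sim_config(seed = 101)
  panel <- simulate_panel(cfg)
  expect_length(panel$genes, 395)
  expect_length(panel$hk_genes, 10)
  expect_equal(sort(unique(unname(panel$category))), sort(panel_categories()))
  expect_true(all(panel$hk_baseline_rpm > 0))
  # signature classes resolve on the simulated panel
  for (sig in default_signatures()) {
    expect_true(all(sig$member_genes %in% panel$genes))
  }

  panel2 <- simulate_panel(sim_config(seed = 101))
  expect_identical(panel, panel2)

  expect_error(sim_config(seed = 1, n_hk = 0), "at least 6")
  expect_error(sim_config(seed = 1, n_hk = 50, n_genes = 40), "exceed")
  expect_error(sim_config(), "seed")
})

test_that("simulated counts match the cohort design and are reproducible", {
  cfg <- sim_config(seed = 103)
  sim <- simulate_counts(cfg)
  expect_equal(ncol(sim$counts$counts), 38)
  expect_equal(nrow(sim$counts$counts), 395)
  expect_length(sim$counts$ntc, 395)
  expect_equal(sum(sim$metadata$tissue == "BM"), 25)
  expect_equal(sum(sim$metadata$paired & sim$metadata$tissue == "adjacent"), 13)
  tab <- table(sim$metadata$primary_cancer[sim$metadata$tissue == "BM"])
  expect_equal(unname(tab[c("lung", "breast", "colorectal")]),
               as.integer(c(12, 6, 7)), ignore_attr = TRUE)
  expect_equal(nrow(sim$truth), 0)

  sim2 <- simulate_counts(sim_config(seed = 103))
  expect_identical(sim$counts$counts, sim2$counts$counts)
  expect_identical(sim$metadata, sim2$metadata)
  expect_identical(sim$qc_stats, sim2$qc_stats)

  sim3 <- simulate_counts(sim_config(seed = 104))
  expect_false(identical(sim$counts$counts, sim3$counts$counts))
})

test_that("planted effects are recorded in the truth record and realized in the data", {
  effects <- data.frame(gene = "CD274", cancer = "lung", tissue = "BM",
                        log2_effect = 3, stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 107, dispersion = 0.001, effects = effects)
  sim <- simulate_counts(cfg)
  expect_equal(nrow(sim$truth), 1)
  expect_equal(sim$truth$target, "CD274")
  expect_equal(sim$truth$log2_effect, 3)

  # realized log2 fold change across the 10 lung pairs approaches the
  # planted effect when count noise is negligible
  nm <- normalize_counts(sim$counts, sim$panel, qc_gate(sim$qc_stats))
  logx <- log_transform(nm)
  meta <- sim$metadata
  pts <- meta$patient_id[meta$primary_cancer == "lung" & meta$paired &
                           meta$tissue == "BM"]
  lfc <- mean(logx$log2_nrpm["CD274", paste0(pts, "_BM")] -
                logx$log2_nrpm["CD274", paste0(pts, "_ADJ")])
  expect_lt(abs(lfc - 3), 0.3)

  # signature shifts land on every member of the class
  cfg2 <- sim_config(seed = 109, dispersion = 0.001,
                     signature_shift = data.frame(class = "checkpoint pathway",
                                                  cancer = "lung", shift = 2,
                                                  stringsAsFactors = FALSE))
  sim2 <- simulate_counts(cfg2)
  expect_equal(sim2$truth$kind, "signature")
  nm2 <- normalize_counts(sim2$counts, sim2$panel, qc_gate(sim2$qc_stats))
  logx2 <- log_transform(nm2)
  cls <- sim2$panel$genes[sim2$panel$category == "checkpoint pathway"]
  meta2 <- sim2$metadata
  lung_bm <- meta2$sample_id[meta2$primary_cancer == "lung" & meta2$tissue == "BM"]
  breast_bm <- meta2$sample_id[meta2$primary_cancer == "breast" & meta2$tissue == "BM"]
  gap <- mean(logx2$log2_nrpm[cls, lung_bm]) - mean(logx2$log2_nrpm[cls, breast_bm])
  expect_lt(abs(gap - 2), 0.6)
})

test_that("housekeeping genes are stable and NTC background is low", {
  sim <- simulate_counts(sim_config(seed = 113))
  hk_cv <- apply(sim$counts$counts[sim$panel$hk_genes, ], 1,
                 function(x) sd(log2(x + 1)))
  target_cv <- apply(sim$counts$counts[setdiff(sim$panel$genes,
                                               sim$panel$hk_genes), ], 1,
                     function(x) sd(log2(x + 1)))
  expect_lt(median(hk_cv), median(target_cv))
  expect_lt(mean(sim$counts$ntc), 10)
  # HK ratios recover the library-size factor structure: per-sample medians
  # are positive and centred near 1
  nm <- normalize_counts(sim$counts, sim$panel)
  expect_true(all(nm$norm_ratio > 0))
  expect_lt(abs(median(log2(nm$norm_ratio))), 0.5)
})

test_that("with no planted effects the DEG test is calibrated on generator data", {
  # 50 independent cohorts at default noise settings; fraction of genes at
  # p < .05 in the paired lung contrast should sit in the 99% binomial band
  hits <- 0; total <- 0
  for (r in 1:50) {
    cfg <- sim_config(seed = 9000 + r)
    sim <- simulate_counts(cfg)
    nm <- normalize_counts(sim$counts, sim$panel, qc_gate(sim$qc_stats))
    logx <- log_transform(nm)
    meta <- sim$metadata
    pts <- meta$patient_id[meta$primary_cancer == "lung" & meta$paired &
                             meta$tissue == "BM"]
    ok <- paste0(pts, "_BM") %in% colnames(logx$log2_nrpm) &
      paste0(pts, "_ADJ") %in% colnames(logx$log2_nrpm)
    pts <- pts[ok]
    ct <- make_contrast("p", "paired", paste0(pts, "_BM"), paste0(pts, "_ADJ"))
    mt <- moderated_t(logx, ct)
    hits <- hits + sum(mt$p_value < 0.05, na.rm = TRUE)
    total <- total + sum(!is.na(mt$p_value))
  }
  rate <- hits / total
  band <- 2.576 * sqrt(0.05 * 0.95 / total)
  expect_gte(rate, 0.05 - band)
  expect_lte(rate, 0.05 + band)
})
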