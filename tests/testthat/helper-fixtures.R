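# Small deterministic fixtures shared across test files.

make_test_panel <- function(n_genes = 20, n_hk = 6) {
  genes <- c(sprintf("G%02d", seq_len(n_genes - n_hk)),
             sprintf("HK%d", seq_len(n_hk)))
  hk <- sprintf("HK%d", seq_len(n_hk))
  category <- stats::setNames(
    c(rep("other immune function", n_genes - n_hk),
      rep("housekeeping", n_hk)), genes)
  category[genes[1:2]] <- "checkpoint pathway"
  panel_definition(genes, category, hk,
                   stats::setNames(seq(500, by = 100,
                                       length.out = n_hk), hk))
}

make_test_counts <- function(panel, n_samples = 4, seed = 7,
                             ntc_rate = 5, mean_count = 500) {
  set.seed(seed)
  genes <- panel$genes
  counts <- matrix(rpois(length(genes) * n_samples, mean_count),
                   nrow = length(genes),
                   dimnames = list(genes, sprintf("S%02d", seq_len(n_samples))))
  counts[panel$hk_genes, ] <- rpois(length(panel$hk_genes) * n_samples,
                                    rep(panel$hk_baseline_rpm, n_samples))
  ntc <- stats::setNames(rpois(length(genes), ntc_rate), genes)
  count_matrix(counts, ntc)
}

# Straight-line reimplementation of the three normalization formulas,
# written independently of the package internals (explicit loops).
oracle_nrpm <- function(counts, ntc, hk_genes, hk_baseline) {
  out <- matrix(NA_real_, nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
  for (s in seq_len(ncol(counts))) {
    ratios <- numeric(length(hk_genes))
    for (k in seq_along(hk_genes)) {
      ratios[k] <- counts[hk_genes[k], s] / hk_baseline[hk_genes[k]]
    }
    norm_ratio <- stats::median(ratios)
    for (g in seq_len(nrow(counts))) {
      bg <- counts[g, s] - ntc[rownames(counts)[g]]
      if (bg < 0) bg <- 0
      out[g, s] <- bg / norm_ratio
    }
  }
  out
}

make_paired_logx <- function(n_genes = 50, n_pairs = 5, seed = 11,
                             effect_genes = integer(0), effect = 0) {
  set.seed(seed)
  a <- matrix(rnorm(n_genes * n_pairs, 8, 1), nrow = n_genes)
  b <- matrix(rnorm(n_genes * n_pairs, 8, 1), nrow = n_genes)
  a[effect_genes, ] <- a[effect_genes, ] + effect
  x <- cbind(a, b)
  rownames(x) <- sprintf("G%03d", seq_len(n_genes))
  colnames(x) <- c(sprintf("A%d", seq_len(n_pairs)), sprintf("B%d", seq_len(n_pairs)))
  x
}
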