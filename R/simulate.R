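#' Configuration for the synthetic panel-count generator
#'
#' Describes a cohort and noise model realistic for a targeted amplicon
#' immune panel: negative-binomial counts with log-normal library-size
#' factors, stable housekeeping genes, low Poisson NTC background, a
#' per-patient log-scale random intercept shared by paired samples, and
#' planted log2 effects on designated gene sets.
#'
#' The default cohort mirrors a 25-patient brain-metastasis study: 12 lung,
#' 6 breast and 7 colorectal primaries, with 10 lung and 3 breast patients
#' contributing paired adjacent noncancerous brain tissue.
#'
#' @param n_genes total panel size (housekeeping genes included).
#' @param n_hk number of housekeeping genes (>= 6).
#' @param cohort data.frame with columns `cancer`, `n`, `n_paired`.
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene
#'   baseline expression on the log2-count scale.
#' @param hk_log2_mean,hk_log2_sd distribution of housekeeping baselines.
#' @param hk_noise_sd per-sample biological noise of HK genes (log2 scale;
#'   small, they are stable by construction).
#' @param dispersion negative-binomial dispersion (1/size); 0 gives Poisson.
#' @param within_pair_sd standard deviation of the within-patient BM-minus-
#'   adjacent log2 difference due to biological noise; each sample receives
#'   independent noise of sd `within_pair_sd / sqrt(2)`.
#' @param patient_sd sd of the per-patient, per-gene random intercept shared
#'   by a patient's BM and adjacent samples.
#' @param libsize_sd sd (log2 scale) of the log-normal library-size factors.
#' @param ntc_rate mean Poisson background count in the no-template control.
#' @param effects optional data.frame of planted differential effects with
#'   columns `gene`, `cancer` (`"any"` for all), `tissue` (`"BM"`,
#'   `"adjacent"` or `"any"`), `log2_effect`.
#' @param signature_shift optional data.frame with columns `class`, `cancer`,
#'   `shift`: adds `shift` (log2) to every gene of a functional category in
#'   BM samples of a cancer type.
#' @param seed integer seed; mandatory for reproducibility.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 395, n_hk = 10,
                       cohort = data.frame(
                         cancer = c("lung", "breast", "colorectal"),
                         n = c(12L, 6L, 7L),
                         n_paired = c(10L, 3L, 0L)),
                       baseline_log2_mean = 8, baseline_log2_sd = 2,
                       hk_log2_mean = 10, hk_log2_sd = 0.5,
                       hk_noise_sd = 0.05,
                       dispersion = 0.05,
                       within_pair_sd = 0.5,
                       patient_sd = 0.5,
                       libsize_sd = 0.2,
                       ntc_rate = 5,
                       effects = NULL,
                       signature_shift = NULL,
                       seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for reproducible simulation")
  if (n_hk < 6) stop("n_hk must be at least 6 (QC gate requirement)")
  if (n_hk > n_genes) stop("n_hk cannot exceed n_genes")
  if (any(cohort$n_paired > cohort$n)) stop("n_paired cannot exceed n")
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (!is.null(effects)) {
    stopifnot(all(c("gene", "cancer", "tissue", "log2_effect") %in%
                    colnames(effects)))
    if (any(!is.finite(effects$log2_effect))) stop("effects must be finite")
  }
  structure(list(n_genes = n_genes, n_hk = n_hk, cohort = cohort,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 hk_log2_mean = hk_log2_mean, hk_log2_sd = hk_log2_sd,
                 hk_noise_sd = hk_noise_sd, dispersion = dispersion,
                 within_pair_sd = within_pair_sd, patient_sd = patient_sd,
                 libsize_sd = libsize_sd, ntc_rate = ntc_rate,
                 effects = effects, signature_shift = signature_shift,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Real symbols seeded into the synthetic panel so the default immune
# signatures resolve on simulated data.
sim_named_genes <- function() {
  list("checkpoint pathway" = c("CD274", "PDCD1LG2", "IDO1"),
       "lymphocyte infiltration" = c("PTPN7", "IL10RA", "GZMK", "CD52",
                                     "CD2", "CCR5", "CCL5"),
       "TCR coexpression" = c("GPR18", "IL7R", "CD3G", "CD3D", "CD8B"),
       "type II interferon signaling" = c("CXCL10", "CIITA", "IRF1", "PSMB9"),
       "tumor antigen" = character(0),
       "tumor marker" = c("KIAA0101", "TOP2A", "CCL17"),
       "other immune function" = c("CA4", "NCAM1", "EGR3", "KLF2",
                                   "CX3CR1", "CD226"))
}

sim_hk_symbols <- function(n) {
  real <- c("ABCF1", "G6PD", "GUSB", "HPRT1", "OAZ1", "POLR2A", "SDHA",
            "TBP", "TUBB", "GAPDH")
  if (n <= length(real)) real[seq_len(n)]
  else c(real, sprintf("HK%02d", seq_len(n - length(real))))
}

#' Simulate a panel definition
#'
#' Synthesizes a panel of `n_genes` genes across the eight functional
#' categories (housekeeping included among them), seeding the signature
#' classes with their canonical member symbols. Per-gene baseline log2
#' expression levels are drawn and stored on the panel (attribute
#' `baseline_log2`); the HK baseline RPM profile is set to each HK gene's
#' expected absolute count in a unit-library-size reference sample, so that
#' a reference sample has all HK ratios approximately 1.
#'
#' @param config a [sim_config()].
#' @return a `panel_def` carrying a `baseline_log2` attribute.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_target <- config$n_genes - config$n_hk
  named <- sim_named_genes()
  cats <- names(named)
  # category share of the non-HK genes; remainder goes to "other immune function"
  share <- c("checkpoint pathway" = 0.03, "lymphocyte infiltration" = 0.10,
             "TCR coexpression" = 0.05, "type II interferon signaling" = 0.04,
             "tumor antigen" = 0.10, "tumor marker" = 0.10,
             "other immune function" = 0.58)
  quota <- pmax(round(share * n_target), lengths(named))
  quota[length(quota)] <- n_target - sum(quota[-length(quota)])
  genes <- character(0); category <- character(0)
  synth_i <- 0
  for (k in seq_along(cats)) {
    members <- named[[cats[k]]]
    extra <- quota[k] - length(members)
    if (extra > 0) {
      members <- c(members, sprintf("IMM%04d", synth_i + seq_len(extra)))
      synth_i <- synth_i + extra
    }
    genes <- c(genes, members)
    category <- c(category, rep(cats[k], length(members)))
  }
  hk <- sim_hk_symbols(config$n_hk)
  genes <- c(genes, hk)
  category <- c(category, rep("housekeeping", config$n_hk))
  names(category) <- genes

  mu <- stats::rnorm(length(genes), config$baseline_log2_mean,
                     config$baseline_log2_sd)
  names(mu) <- genes
  mu[hk] <- stats::rnorm(config$n_hk, config$hk_log2_mean, config$hk_log2_sd)

  panel <- panel_definition(genes, category, hk,
                            stats::setNames(2^mu[hk], hk))
  attr(panel, "baseline_log2") <- mu
  panel
}

#' Simulate panel counts, metadata, QC stats and a truth record
#'
#' Draws a full study data set under the generator model described in
#' [sim_config()]. The returned truth record lists every planted
#' differential effect and signature shift so downstream validation never
#' reaches into generator internals.
#'
#' @param config a [sim_config()].
#' @param panel a `panel_def` from [simulate_panel()] (one is simulated from
#'   `config` if omitted).
#' @return list with `counts` (a `count_matrix`), `metadata` (data.frame),
#'   `qc_stats` (data.frame), `truth` (data.frame) and `panel`.
#' @export
simulate_counts <- function(config, panel = simulate_panel(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "panel_def"))
  set.seed(config$seed + 1L)
  genes <- panel$genes
  hk <- panel$hk_genes
  is_hk <- genes %in% hk
  mu <- attr(panel, "baseline_log2")
  if (is.null(mu)) {
    mu <- stats::rnorm(length(genes), config$baseline_log2_mean,
                       config$baseline_log2_sd)
    names(mu) <- genes
    mu[hk] <- log2(panel$hk_baseline_rpm)
  }

  # cohort layout
  meta <- do.call(rbind, lapply(seq_len(nrow(config$cohort)), function(i) {
    row <- config$cohort[i, ]
    data.frame(cancer = row$cancer, idx = seq_len(row$n),
               paired = seq_len(row$n) <= row$n_paired,
               stringsAsFactors = FALSE)
  }))
  meta$patient_id <- sprintf("P%02d", seq_len(nrow(meta)))
  ages <- round(stats::runif(nrow(meta), 30, 85))
  genders <- ifelse(meta$cancer == "breast", "female",
                    sample(c("male", "female"), nrow(meta), TRUE, c(0.65, 0.35)))
  treat <- stats::runif(nrow(meta)) < 0.4

  rows <- list()
  for (i in seq_len(nrow(meta))) {
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = paste0(meta$patient_id[i], "_BM"),
      patient_id = meta$patient_id[i], primary_cancer = meta$cancer[i],
      tissue = "BM", age = ages[i], gender = genders[i],
      prior_treatment = treat[i], stringsAsFactors = FALSE)
    if (meta$paired[i]) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = paste0(meta$patient_id[i], "_ADJ"),
        patient_id = meta$patient_id[i], primary_cancer = meta$cancer[i],
        tissue = "adjacent", age = ages[i], gender = genders[i],
        prior_treatment = treat[i], stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  n_s <- nrow(samples)
  n_g <- length(genes)

  # per-patient per-gene random intercept, shared by paired tissues
  pint <- matrix(stats::rnorm(nrow(meta) * n_g, 0, config$patient_sd),
                 nrow = n_g, dimnames = list(genes, meta$patient_id))
  pint[is_hk, ] <- 0

  noise_sd <- ifelse(is_hk, config$hk_noise_sd,
                     config$within_pair_sd / sqrt(2))
  libsize <- 2^stats::rnorm(n_s, 0, config$libsize_sd)

  eta <- matrix(mu[genes], nrow = n_g, ncol = n_s,
                dimnames = list(genes, samples$sample_id))
  eta <- eta + pint[, samples$patient_id]
  eta <- eta + matrix(stats::rnorm(n_g * n_s, 0, noise_sd), nrow = n_g)

  truth <- data.frame(kind = character(0), target = character(0),
                      cancer = character(0), tissue = character(0),
                      log2_effect = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(config$effects)) {
    for (i in seq_len(nrow(config$effects))) {
      ef <- config$effects[i, ]
      if (!ef$gene %in% genes) stop("planted effect gene not in panel: ", ef$gene)
      sel <- (ef$cancer == "any" | samples$primary_cancer == ef$cancer) &
        (ef$tissue == "any" | samples$tissue == ef$tissue)
      eta[ef$gene, sel] <- eta[ef$gene, sel] + ef$log2_effect
      truth <- rbind(truth, data.frame(kind = "deg", target = ef$gene,
                                       cancer = ef$cancer, tissue = ef$tissue,
                                       log2_effect = ef$log2_effect,
                                       stringsAsFactors = FALSE))
    }
  }
  if (!is.null(config$signature_shift)) {
    for (i in seq_len(nrow(config$signature_shift))) {
      sh <- config$signature_shift[i, ]
      cls_genes <- genes[panel$category == sh$class]
      sel <- samples$primary_cancer == sh$cancer & samples$tissue == "BM"
      eta[cls_genes, sel] <- eta[cls_genes, sel] + sh$shift
      truth <- rbind(truth, data.frame(kind = "signature", target = sh$class,
                                       cancer = sh$cancer, tissue = "BM",
                                       log2_effect = sh$shift,
                                       stringsAsFactors = FALSE))
    }
  }

  mean_mat <- sweep(2^eta, 2, libsize, `*`)
  counts <- matrix(0L, n_g, n_s, dimnames = dimnames(eta))
  if (config$dispersion > 0) {
    counts[] <- stats::rnbinom(n_g * n_s, mu = mean_mat,
                               size = 1 / config$dispersion)
  } else {
    counts[] <- stats::rpois(n_g * n_s, lambda = mean_mat)
  }
  ntc <- stats::setNames(stats::rpois(n_g, config$ntc_rate), genes)
  cm <- count_matrix(counts, ntc)

  on_target <- stats::runif(n_s, 0.72, 0.92)
  qc <- data.frame(sample_id = samples$sample_id,
                   mapped_reads = unname(round(colSums(counts) / on_target)),
                   on_target_ratio = round(on_target, 4),
                   n_hk_detected = unname(colSums(counts[hk, , drop = FALSE] > 0)),
                   stringsAsFactors = FALSE)

  list(counts = cm, metadata = validate_metadata(samples), qc_stats = qc,
       truth = truth, panel = panel)
}

#' Corrupt QC statistics to exercise the QC gate
#'
#' @param stats QC stats data.frame.
#' @param mode one of `"low_depth"` (mapped reads below 200k),
#'   `"off_target"` (on-target ratio below 50%), `"hk_dropout"` (5 detected
#'   HK genes).
#' @param samples sample ids to corrupt.
#' @return the modified data.frame; untouched rows are unchanged.
#' @export
corrupt_qc <- function(stats, mode, samples) {
  if (!mode %in% c("low_depth", "off_target", "hk_dropout"))
    stop("unknown corruption mode: ", mode)
  miss <- setdiff(samples, stats$sample_id)
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  i <- stats$sample_id %in% samples
  switch(mode,
         low_depth = { stats$mapped_reads[i] <- 150000L },
         off_target = { stats$on_target_ratio[i] <- 0.45 },
         hk_dropout = { stats$n_hk_detected[i] <- 5L })
  stats
}
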