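#' Apply the sequencing QC gate
#'
#' A sample passes only if all three criteria hold: mapped reads >= 200,000,
#' on-target ratio strictly greater than 50%, and at least 6 housekeeping
#' genes detected. The verdict enumerates every failed criterion; exactly
#' 50.0% on-target fails (the bound is strict) while exactly 200,000 mapped
#' reads and exactly 6 detected HK genes pass.
#'
#' @param stats QC stats data.frame (see [read_qc_stats()]).
#' @param min_mapped minimum mapped read count (inclusive).
#' @param min_on_target on-target ratio bound (exclusive).
#' @param min_hk minimum number of detected housekeeping genes (inclusive).
#' @return data.frame with `sample_id`, `pass`, and `reasons` (semicolon-joined
#'   labels of the failed criteria, empty string when passing).
#' @export
qc_gate <- function(stats, min_mapped = 2e5, min_on_target = 0.5, min_hk = 6) {
  reasons <- vapply(seq_len(nrow(stats)), function(i) {
    r <- character(0)
    if (stats$mapped_reads[i] < min_mapped) r <- c(r, "mapped_reads")
    if (stats$on_target_ratio[i] <= min_on_target) r <- c(r, "on_target_ratio")
    if (stats$n_hk_detected[i] < min_hk) r <- c(r, "n_hk_detected")
    paste(r, collapse = ";")
  }, character(1))
  data.frame(sample_id = stats$sample_id, pass = reasons == "",
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Subtract no-template-control background from absolute read counts
#'
#' Each gene's NTC count is subtracted from every clinical sample's count for
#' that gene; negative results are clamped to 0 so downstream log transforms
#' stay defined.
#'
#' @param cm a `count_matrix`.
#' @return gene x sample numeric matrix of background-subtracted counts.
#' @export
subtract_background <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  pmax(cm$counts - cm$ntc[rownames(cm$counts)], 0)
}

#' Housekeeping-gene calibration ratios
#'
#' For each sample, each HK gene's absolute (pre-subtraction) read count is
#' divided by its baseline RPM profile value:
#' ratio = absolute HK count / baseline HK RPM. HK genes with zero counts
#' contribute a ratio of 0 (they also count against the QC gate's detected-HK
#' criterion).
#'
#' @param cm a `count_matrix`.
#' @param panel a `panel_def`.
#' @return HK gene x sample matrix of ratios.
#' @export
hk_ratios <- function(cm, panel) {
  stopifnot(inherits(cm, "count_matrix"), inherits(panel, "panel_def"))
  hk <- intersect(panel$hk_genes, rownames(cm$counts))
  if (length(hk) == 0) stop("no housekeeping genes present in count matrix")
  sweep(cm$counts[hk, , drop = FALSE], 1, panel$hk_baseline_rpm[hk], `/`)
}

#' Normalize absolute read counts to nRPM
#'
#' Implements the housekeeping-ratio normalization: the per-sample
#' normalization ratio is the median of the sample's HK ratios
#' (absolute HK count / baseline HK RPM), and
#' nRPM(sample, gene) = background-subtracted count / normalization ratio.
#' Samples failing QC (when verdicts are given) are excluded, as is any
#' sample whose normalization ratio is zero (division undefined; a warning
#' names it).
#'
#' @param cm a `count_matrix`.
#' @param panel a `panel_def`.
#' @param verdicts optional QC verdict data.frame from [qc_gate()]; only
#'   passing samples are normalized.
#' @return an object of class `nrpm_matrix` with elements `nrpm` (gene x
#'   sample matrix), `norm_ratio` (named per-sample normalization ratios) and
#'   `hk_ratios` (HK gene x sample matrix).
#' @export
normalize_counts <- function(cm, panel, verdicts = NULL) {
  stopifnot(inherits(cm, "count_matrix"), inherits(panel, "panel_def"))
  keep <- cm$sample_ids
  if (!is.null(verdicts)) {
    passing <- verdicts$sample_id[verdicts$pass]
    keep <- intersect(keep, passing)
  }
  if (length(keep) == 0) stop("no QC-passing samples to normalize")
  sub <- count_matrix(cm$counts[, keep, drop = FALSE], cm$ntc)
  hk <- hk_ratios(sub, panel)
  ratio <- apply(hk, 2, stats::median)
  zero <- names(ratio)[ratio <= 0]
  if (length(zero)) {
    warning("normalization ratio is 0 for sample(s) ",
            paste(zero, collapse = ", "), "; excluded (cannot divide)")
    keep <- setdiff(keep, zero)
    if (length(keep) == 0) stop("no samples with positive normalization ratio")
    sub <- count_matrix(cm$counts[, keep, drop = FALSE], cm$ntc)
    hk <- hk[, keep, drop = FALSE]
    ratio <- ratio[keep]
  }
  bg <- subtract_background(sub)
  nrpm <- sweep(bg, 2, ratio, `/`)
  structure(list(nrpm = nrpm, norm_ratio = ratio, hk_ratios = hk),
            class = "nrpm_matrix")
}

#' @export
print.nrpm_matrix <- function(x, ...) {
  cat("nRPM matrix:", nrow(x$nrpm), "genes x", ncol(x$nrpm), "samples\n")
  cat("normalization ratios:",
      paste(sprintf("%s=%.3g", names(x$norm_ratio), x$norm_ratio),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write an nRPM matrix to TSV at full float precision
#' @param nm an `nrpm_matrix` or plain gene x sample matrix.
#' @param path output path.
#' @export
write_nrpm <- function(nm, path) {
  mat <- if (inherits(nm, "nrpm_matrix")) nm$nrpm else nm
  df <- data.frame(gene = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample expression matrix (nRPM or raw) from TSV
#' @param path TSV with a leading `gene` column.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}
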