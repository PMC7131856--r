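#' Render figure analogues for a pipeline run
#'
#' Writes static PNG files: a volcano plot for the first unpaired contrast
#' (x = log2 FC, y = -log10 p, DEGs colored by direction), a row-clustered
#' heatmap of DEG expression (average linkage on Euclidean distance of
#' z-scored log2 nRPM), Venn diagrams for each overlap, a PCA scatter of BM
#' samples colored by cancer type, and per-gene boxplots of checkpoint-gene
#' nRPM by cancer type. A contrast with zero DEGs skips its heatmap with a
#' notice.
#'
#' @param run a `panel_run` from [run_pipeline()].
#' @param outdir directory for the PNG files.
#' @param width,height device size in inches.
#' @return invisible character vector of the files written.
#' @export
render_figures <- function(run, outdir, width = 7, height = 6) {
  stopifnot(inherits(run, "panel_run"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  unpaired <- grep("_BM_vs_", names(run$deg), value = TRUE, invert = TRUE)
  if (length(unpaired)) {
    files <- c(files, fig_volcano(run$deg[[unpaired[1]]], unpaired[1],
                                  run$report$thresholds, outdir, width, height))
    files <- c(files, fig_heatmap(run, unpaired[1], outdir))
  }
  for (nm in names(run$venn)) {
    files <- c(files, fig_venn(run$venn[[nm]], nm, outdir, width, height))
  }
  if (!is.null(run$pca)) files <- c(files, fig_pca(run, outdir, width, height))
  files <- c(files, fig_boxplots(run, outdir, width, height))
  invisible(files)
}

fig_volcano <- function(deg, name, thresholds, outdir, width, height) {
  df <- deg[!is.na(deg$p_value), ]
  df$neglog10p <- -log10(pmax(df$p_value, 1e-300))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc, y = .data$neglog10p,
                                        color = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::scale_color_manual(values = c(up = "#c0392b", down = "#2471a3",
                                           none = "grey70")) +
    ggplot2::geom_hline(yintercept = -log10(thresholds$p), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(thresholds$fc), linetype = 2) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = paste("Volcano:", name)) +
    ggplot2::theme_bw()
  path <- file.path(outdir, paste0("volcano_", name, ".png"))
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 120)
  path
}

fig_heatmap <- function(run, name, outdir) {
  deg <- run$deg[[name]]
  genes <- deg$gene[deg$is_deg]
  if (!length(genes)) {
    message("heatmap skipped for '", name, "': no DEGs called")
    return(character(0))
  }
  meta <- run$metadata
  bm <- meta$sample_id[meta$tissue == "BM" &
                         meta$sample_id %in% colnames(run$logx$log2_nrpm)]
  mat <- run$logx$log2_nrpm[genes, bm, drop = FALSE]
  keep <- apply(mat, 1, stats::sd) > 0
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 2) {
    message("heatmap skipped for '", name, "': fewer than 2 variable DEGs")
    return(character(0))
  }
  ann <- data.frame(cancer = meta$primary_cancer[match(bm, meta$sample_id)],
                    row.names = bm)
  path <- file.path(outdir, paste0("heatmap_", name, ".png"))
  grDevices::png(path, width = 900, height = 150 + 14 * nrow(mat), res = 110)
  pheatmap::pheatmap(mat, scale = "row",
                     clustering_distance_rows = "euclidean",
                     clustering_method = "average",
                     annotation_col = ann, fontsize_row = 6,
                     main = paste("DEGs:", name))
  grDevices::dev.off()
  path
}

# 2- or 3-circle Venn drawn with base grid arithmetic (counts per region).
fig_venn <- function(venn, name, outdir, width, height) {
  path <- file.path(outdir, paste0("venn_", name, ".png"))
  grDevices::png(path, width = width * 110, height = height * 110, res = 110)
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 10), ylim = c(0, 10), asp = 1)
  graphics::title(main = paste("Overlap:", name))
  k <- length(venn$labels)
  circ <- function(cx, cy, r, col) {
    th <- seq(0, 2 * pi, length.out = 200)
    graphics::polygon(cx + r * cos(th), cy + r * sin(th),
                      col = grDevices::adjustcolor(col, 0.35), border = col)
  }
  cols <- c("#c0392b", "#2471a3", "#1e8449")
  if (k == 2) {
    centers <- list(c(4, 5), c(6, 5))
    text_at <- list(c(3, 5), c(7, 5), c(5, 5))
    masks <- c(paste0(venn$labels[1], "_only"), paste0(venn$labels[2], "_only"),
               paste(venn$labels, collapse = "&"))
    lab_at <- list(c(3, 7.6), c(7, 7.6))
  } else {
    centers <- list(c(4.2, 6), c(5.8, 6), c(5, 4.4))
    text_at <- list(c(3.3, 6.5), c(6.7, 6.5), c(5, 3.5),
                    c(5, 6.7), c(4, 4.8), c(6, 4.8), c(5, 5.5))
    l <- venn$labels
    masks <- c(paste0(l[1], "_only"), paste0(l[2], "_only"), paste0(l[3], "_only"),
               paste(l[1:2], collapse = "&"),
               paste(l[c(1, 3)], collapse = "&"),
               paste(l[2:3], collapse = "&"),
               paste(l, collapse = "&"))
    lab_at <- list(c(2.8, 8.2), c(7.2, 8.2), c(5, 2.2))
  }
  for (i in seq_len(k)) {
    circ(centers[[i]][1], centers[[i]][2], 2.2, cols[i])
    graphics::text(lab_at[[i]][1], lab_at[[i]][2], venn$labels[i], cex = 0.9)
  }
  for (i in seq_along(masks)) {
    graphics::text(text_at[[i]][1], text_at[[i]][2],
                   venn$counts[[masks[i]]], cex = 1.1)
  }
  grDevices::dev.off()
  path
}

fig_pca <- function(run, outdir, width, height) {
  coords <- run$pca$coords
  meta <- run$metadata
  coords$cancer <- meta$primary_cancer[match(coords$sample_id, meta$sample_id)]
  ve <- run$pca$var_explained
  p <- ggplot2::ggplot(coords, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                            color = .data$cancer)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
                  title = "PCA of BM samples on overlap DEGs") +
    ggplot2::theme_bw()
  path <- file.path(outdir, "pca_bm_samples.png")
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 120)
  path
}

fig_boxplots <- function(run, outdir, width, height) {
  genes <- intersect(default_signatures()[["checkpoint pathway"]]$member_genes,
                     rownames(run$nrpm$nrpm))
  if (!length(genes)) return(character(0))
  meta <- run$metadata
  bm <- meta$sample_id[meta$tissue == "BM" &
                         meta$sample_id %in% colnames(run$nrpm$nrpm)]
  df <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene = g, nrpm = run$nrpm$nrpm[g, bm],
               cancer = meta$primary_cancer[match(bm, meta$sample_id)],
               stringsAsFactors = FALSE)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cancer, y = .data$nrpm,
                                        fill = .data$cancer)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "nRPM",
                  title = "Checkpoint-pathway gene expression by cancer type") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
  path <- file.path(outdir, "boxplot_checkpoint_genes.png")
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 120)
  path
}
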