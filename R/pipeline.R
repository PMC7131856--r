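#' Orchestrate the full panel analysis pipeline
#'
#' Runs, in order: QC gating, nRPM normalization, log2 transform, paired
#' BM-vs-adjacent contrasts per cancer type (where at least 2 pairs exist),
#' unpaired BM contrasts of the case cancer type against each other type,
#' co-regulation Venn overlaps, signature scoring and covariate-adjusted
#' association, and a PCA embedding on the overlap gene set. Input is either
#' a [sim_config()] (data are simulated) or a list with elements `counts`
#' (a `count_matrix`), `panel`, `metadata`, `qc_stats`.
#'
#' @param input a `sim_config` or a list of prepared objects.
#' @param fc_threshold,p_threshold DEG calling thresholds.
#' @param pseudocount offset for the log2 transform.
#' @param case,control cancer types for the signature association outcome.
#' @param outdir optional directory; when given, the report (JSON), nRPM
#'   matrix, DEG tables, Venn regions, signature associations and truth
#'   record (if simulated) are written there as diffable text artifacts.
#' @return object of class `panel_run`: list with `report` (summary), the
#'   intermediate objects (`nrpm`, `logx`, `deg`, `venn`, `scores`,
#'   `association`, `pca`, `qc`) and the inputs.
#' @export
run_pipeline <- function(input, fc_threshold = 2, p_threshold = 0.05,
                         pseudocount = 1, case = "lung", control = "breast",
                         outdir = NULL) {
  if (inherits(input, "sim_config")) {
    sim <- simulate_counts(input)
    provenance <- list(source = "simulation", seed = input$seed)
  } else {
    sim <- input
    provenance <- list(source = "supplied data", seed = NA)
  }
  for (el in c("counts", "panel", "metadata", "qc_stats")) {
    if (is.null(sim[[el]])) stop("pipeline input missing element: ", el)
  }
  provenance$config_hash <- hash_object(
    list(fc_threshold, p_threshold, pseudocount, case, control,
         if (inherits(input, "sim_config")) unclass(input) else NULL))
  provenance$package_version <- as.character(utils::packageVersion("immunopanel"))

  verdicts <- qc_gate(sim$qc_stats)
  nrpm <- normalize_counts(sim$counts, sim$panel, verdicts)
  logx <- log_transform(nrpm, pseudocount)
  meta <- sim$metadata[sim$metadata$sample_id %in% colnames(logx$log2_nrpm), ]

  contrasts <- build_default_contrasts(meta, case = case)
  deg <- lapply(contrasts, function(ct)
    run_deg(logx, ct, fc_threshold, p_threshold))
  names(deg) <- vapply(contrasts, `[[`, character(1), "name")

  venn <- list()
  paired_names <- grep("_BM_vs_adjacent$", names(deg), value = TRUE)
  if (length(paired_names) >= 2) {
    up <- lapply(deg[paired_names[1:2]], function(d) d$gene[d$is_deg & d$direction == "up"])
    dn <- lapply(deg[paired_names[1:2]], function(d) d$gene[d$is_deg & d$direction == "down"])
    venn$co_upregulated <- venn_overlap(up)
    venn$co_downregulated <- venn_overlap(dn)
  }
  unpaired_names <- grep("_BM_vs_", names(deg), value = TRUE, invert = TRUE)
  if (length(unpaired_names) >= 2) {
    degsets <- lapply(deg[unpaired_names[1:2]], function(d) d$gene[d$is_deg])
    venn$cross_type_degs <- venn_overlap(degsets)
  }

  scores <- tryCatch(score_signatures(logx), error = function(e) NULL)
  association <- if (!is.null(scores) &&
                     sum(meta$tissue == "BM" & meta$primary_cancer == case) > 0 &&
                     sum(meta$tissue == "BM" & meta$primary_cancer == control) > 0) {
    associate_signatures(scores, meta, case = case, control = control)
  } else NULL

  pca_genes <- if (!is.null(venn$cross_type_degs)) {
    both <- venn$cross_type_degs$regions[[paste(unpaired_names[1:2], collapse = "&")]]
    if (length(both) >= 2) both else NULL
  } else NULL
  bm_ids <- meta$sample_id[meta$tissue == "BM"]
  pca <- tryCatch(
    pca_embedding(logx$log2_nrpm[, bm_ids, drop = FALSE], genes = pca_genes),
    error = function(e) NULL)

  report <- list(
    provenance = provenance,
    qc = list(n_samples = nrow(sim$qc_stats),
              n_pass = sum(verdicts$pass),
              excluded = verdicts$sample_id[!verdicts$pass]),
    thresholds = list(fc = fc_threshold, p = p_threshold,
                      pseudocount = pseudocount),
    deg_counts = lapply(deg, function(d)
      list(n_deg = sum(d$is_deg), up = sum(d$direction == "up"),
           down = sum(d$direction == "down"))),
    venn_counts = lapply(venn, function(v) as.list(v$counts)),
    association = if (!is.null(association))
      association[, c("signature", "coef", "se", "p_value", "converged")]
      else NULL,
    pca_var_explained = if (!is.null(pca)) pca$var_explained else NULL
  )

  run <- structure(list(report = report, qc = verdicts, nrpm = nrpm,
                        logx = logx, deg = deg, venn = venn, scores = scores,
                        association = association, pca = pca,
                        counts = sim$counts, panel = sim$panel,
                        metadata = sim$metadata, qc_stats = sim$qc_stats,
                        truth = sim$truth),
                   class = "panel_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

# Paired BM-vs-adjacent contrast per cancer type with >= 2 pairs, then
# unpaired case-vs-other BM contrasts.
build_default_contrasts <- function(meta, case = "lung") {
  out <- list()
  for (cc in unique(meta$primary_cancer)) {
    sub <- meta[meta$primary_cancer == cc & meta$paired, ]
    pts <- intersect(sub$patient_id[sub$tissue == "BM"],
                     sub$patient_id[sub$tissue == "adjacent"])
    if (length(pts) >= 2) {
      a <- sub$sample_id[match(paste(pts, "BM"), paste(sub$patient_id, sub$tissue))]
      b <- sub$sample_id[match(paste(pts, "adjacent"), paste(sub$patient_id, sub$tissue))]
      out[[length(out) + 1]] <- make_contrast(
        paste0(cc, "_BM_vs_adjacent"), "paired", a, b, pairing = pts)
    }
  }
  bm <- meta[meta$tissue == "BM", ]
  others <- setdiff(unique(bm$primary_cancer), case)
  for (oc in others) {
    ga <- bm$sample_id[bm$primary_cancer == case]
    gb <- bm$sample_id[bm$primary_cancer == oc]
    if (length(ga) >= 2 && length(gb) >= 2) {
      out[[length(out) + 1]] <- make_contrast(
        paste0(case, "_vs_", oc), "unpaired", ga, gb)
    }
  }
  out
}

#' @export
print.panel_run <- function(x, ...) {
  r <- x$report
  cat("Panel pipeline run\n")
  cat("  QC:", r$qc$n_pass, "of", r$qc$n_samples, "samples pass\n")
  for (nm in names(r$deg_counts)) {
    dc <- r$deg_counts[[nm]]
    cat(sprintf("  %-28s %d DEGs (%d up, %d down)\n", nm, dc$n_deg, dc$up, dc$down))
  }
  if (!is.null(r$association)) {
    cat("  Signature association (", r$provenance$source, "):\n", sep = "")
    print(r$association, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(run$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  write_nrpm(run$nrpm, file.path(outdir, "nrpm.tsv"))
  for (nm in names(run$deg)) {
    utils::write.table(run$deg[[nm]],
                       file.path(outdir, paste0("deg_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(run$venn)) {
    v <- run$venn[[nm]]
    df <- do.call(rbind, lapply(names(v$regions), function(lbl) {
      if (!length(v$regions[[lbl]])) return(NULL)
      data.frame(region = lbl, gene = v$regions[[lbl]], stringsAsFactors = FALSE)
    }))
    if (is.null(df)) df <- data.frame(region = character(0), gene = character(0))
    utils::write.table(df, file.path(outdir, paste0("venn_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$association)) {
    utils::write.table(run$association, file.path(outdir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$truth) && nrow(run$truth)) {
    utils::write.table(run$truth, file.path(outdir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Load an expression profile TSV, auto-detecting raw counts vs nRPM
#'
#' Deposited panel expression tables may hold either absolute read counts
#' (which need background subtraction and HK-ratio normalization) or
#' already-normalized nRPM values. This loader detects which: non-integer
#' values, a missing NTC column, or per-sample HK-ratio medians already close
#' to 1 indicate normalized data (returned as-is); otherwise the full
#' normalization is applied.
#'
#' @param path TSV with a `gene` column and one column per sample.
#' @param panel a `panel_def`.
#' @param ntc_id no-template-control column name.
#' @param tol relative tolerance on the HK-ratio medians for the
#'   "already normalized" call.
#' @return list with `nrpm` (gene x sample matrix), `detected`
#'   (`"normalized"` or `"raw"`).
#' @export
read_expression_profile <- function(path, panel, ntc_id = "NTC", tol = 0.25) {
  mat <- read_expression_tsv(path)
  has_ntc <- ntc_id %in% colnames(mat)
  integral <- all(abs(mat - round(mat)) < 1e-8)
  already <- FALSE
  if (!integral || !has_ntc) {
    already <- TRUE
  } else {
    hk <- intersect(panel$hk_genes, rownames(mat))
    samp <- setdiff(colnames(mat), ntc_id)
    med <- apply(sweep(mat[hk, samp, drop = FALSE], 1,
                       panel$hk_baseline_rpm[hk], `/`), 2, stats::median)
    if (all(abs(log2(pmax(med, 1e-12))) < log2(1 + tol))) already <- TRUE
  }
  if (already) {
    samp <- setdiff(colnames(mat), if (has_ntc) ntc_id else character(0))
    return(list(nrpm = mat[, samp, drop = FALSE], detected = "normalized"))
  }
  cm <- count_matrix(mat[, setdiff(colnames(mat), ntc_id), drop = FALSE],
                     mat[, ntc_id])
  list(nrpm = normalize_counts(cm, panel)$nrpm, detected = "raw")
}
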