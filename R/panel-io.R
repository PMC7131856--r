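#' Functional categories recognised by the panel
#'
#' The panel assigns every gene to exactly one functional category. Four of
#' these (checkpoint pathway, lymphocyte infiltration, TCR coexpression,
#' type II interferon signaling) double as immune signature classes.
#'
#' @export
panel_categories <- function() {
  c("checkpoint pathway", "lymphocyte infiltration", "TCR coexpression",
    "type II interferon signaling", "tumor antigen", "tumor marker",
    "other immune function", "housekeeping")
}

#' Construct a validated panel definition
#'
#' A panel definition is the static description of a targeted expression
#' panel: its gene universe, the functional category of each gene, the
#' housekeeping (HK) genes used as endogenous controls, and the baseline
#' reads-per-million profile each HK gene is compared against during
#' normalization.
#'
#' @param genes character vector of gene symbols (the full panel).
#' @param category named character vector mapping every gene to one of
#'   [panel_categories()].
#' @param hk_genes character vector of housekeeping gene symbols, a subset of
#'   `genes`; at least 6 are required (the QC gate needs >= 6 detected).
#' @param hk_baseline_rpm named numeric vector giving each HK gene's strictly
#'   positive baseline RPM (established from replicate runs of a reference
#'   cell line).
#' @return an object of class `panel_def`.
#' @export
panel_definition <- function(genes, category, hk_genes, hk_baseline_rpm) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols in panel: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (!all(names(category) %in% genes) || !setequal(names(category), genes)) {
    stop("category map must cover every panel gene exactly once")
  }
  bad_cat <- setdiff(unique(category), panel_categories())
  if (length(bad_cat)) {
    stop("unknown categories: ", paste(bad_cat, collapse = ", "))
  }
  hk_genes <- as.character(hk_genes)
  if (!all(hk_genes %in% genes)) {
    stop("housekeeping genes absent from panel: ",
         paste(setdiff(hk_genes, genes), collapse = ", "))
  }
  if (length(hk_genes) < 6) {
    stop("panel must declare at least 6 housekeeping genes")
  }
  missing_base <- setdiff(hk_genes, names(hk_baseline_rpm))
  if (length(missing_base)) {
    stop("missing HK baseline RPM for: ", paste(missing_base, collapse = ", "))
  }
  hk_baseline_rpm <- hk_baseline_rpm[hk_genes]
  if (any(!is.finite(hk_baseline_rpm)) || any(hk_baseline_rpm <= 0)) {
    bad <- hk_genes[!is.finite(hk_baseline_rpm) | hk_baseline_rpm <= 0]
    stop("non-positive HK baseline RPM for: ", paste(bad, collapse = ", "))
  }
  structure(
    list(genes = genes, category = category[genes],
         hk_genes = hk_genes, hk_baseline_rpm = hk_baseline_rpm),
    class = "panel_def"
  )
}

#' @export
print.panel_def <- function(x, ...) {
  cat("Panel definition:", length(x$genes), "genes,",
      length(x$hk_genes), "housekeeping genes\n")
  tab <- table(x$category)
  for (nm in names(tab)) cat(sprintf("  %-30s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Write a panel definition to a YAML file
#'
#' @param panel a `panel_def`.
#' @param path output file path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_def"))
  yaml::write_yaml(
    list(genes = as.list(panel$genes),
         category = as.list(panel$category),
         hk_genes = as.list(panel$hk_genes),
         hk_baseline_rpm = as.list(panel$hk_baseline_rpm)),
    path, precision = 15
  )
  invisible(path)
}

#' Read a panel definition from a YAML file
#'
#' @param path path to a YAML panel file as written by [write_panel()].
#' @return a validated `panel_def`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- yaml::read_yaml(path)
  for (field in c("genes", "category", "hk_genes", "hk_baseline_rpm")) {
    if (is.null(raw[[field]])) stop("panel file missing field: ", field)
  }
  panel_definition(
    genes = unlist(raw$genes),
    category = unlist(raw$category),
    hk_genes = unlist(raw$hk_genes),
    hk_baseline_rpm = unlist(raw$hk_baseline_rpm)
  )
}

#' Construct a count matrix with its no-template control
#'
#' @param counts gene x sample matrix of non-negative integer absolute read
#'   counts (rownames = genes, colnames = sample ids).
#' @param ntc named numeric vector of no-template-control counts, one per gene.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, ntc) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames")
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicated sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  }
  check_counts_integral(counts, "counts")
  ntc <- ntc[rownames(counts)]
  if (any(is.na(ntc))) stop("NTC vector must cover every gene")
  check_counts_integral(matrix(ntc, dimnames = list(rownames(counts), "NTC")),
                        "NTC")
  structure(list(counts = counts, ntc = stats::setNames(as.numeric(ntc), rownames(counts)),
                 sample_ids = colnames(counts)),
            class = "count_matrix")
}

check_counts_integral <- function(x, what) {
  if (any(is.na(x))) stop(what, " contains missing values")
  if (any(x < 0)) stop(what, " contains negative values")
  if (any(abs(x - round(x)) > 1e-8)) {
    stop(what, " contains non-integer values (absolute read counts required)")
  }
  invisible(TRUE)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Count matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (+ NTC)\n")
  invisible(x)
}

#' Read an absolute-read-count matrix from TSV
#'
#' The TSV has a `gene` column followed by one column per sample; the
#' no-template control must be present as a column named `NTC` (or as named
#' by `ntc_id`). Genes are reordered to panel order. Genes in the file but
#' not in the panel are dropped with a warning; panel genes missing from the
#' file are reported with a warning.
#'
#' @param path TSV path.
#' @param panel a `panel_def`.
#' @param ntc_id column name identifying the no-template control.
#' @return a `count_matrix` (NTC removed from the sample columns).
#' @export
read_counts <- function(path, panel, ntc_id = "NTC") {
  stopifnot(inherits(panel, "panel_def"))
  if (!file.exists(path)) stop("counts file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1])) {
    stop("duplicated sample column(s): ",
         paste(unique(header[-1][duplicated(header[-1])]), collapse = ", "))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(colnames(df)[1], "gene")) {
    stop("first column of a counts TSV must be named 'gene'")
  }
  if (!ntc_id %in% colnames(df)) {
    stop("no-template control column '", ntc_id, "' missing from counts file")
  }
  genes <- df$gene
  if (anyDuplicated(genes)) stop("duplicated gene rows in counts file")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- genes
  extra <- setdiff(genes, panel$genes)
  if (length(extra)) {
    warning("dropping ", length(extra),
            " gene(s) absent from the panel: ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "")
    mat <- mat[setdiff(genes, extra), , drop = FALSE]
  }
  missing <- setdiff(panel$genes, rownames(mat))
  if (length(missing)) {
    warning(length(missing), " panel gene(s) missing from counts file: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
  }
  ord <- intersect(panel$genes, rownames(mat))
  mat <- mat[ord, , drop = FALSE]
  ntc <- mat[, ntc_id]
  mat <- mat[, setdiff(colnames(mat), ntc_id), drop = FALSE]
  count_matrix(mat, ntc)
}

#' Write a count matrix (with NTC column) to TSV
#'
#' @param cm a `count_matrix`.
#' @param path output path.
#' @param ntc_id column name for the no-template control.
#' @export
write_counts <- function(cm, path, ntc_id = "NTC") {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[[ntc_id]] <- cm$ntc
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata from TSV
#'
#' Expects columns `sample_id`, `patient_id`, `primary_cancer` (lung, breast
#' or colorectal), `tissue` (BM or adjacent), `age`, `gender` (male/female),
#' `prior_treatment` (logical). Adjacent-tissue samples whose patient has no
#' matching BM sample are flagged (`paired = FALSE`) with a warning; they are
#' excluded from paired contrasts downstream.
#'
#' @param path TSV path.
#' @return a data.frame of validated sample metadata with a `paired` column.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate a sample metadata data.frame
#'
#' @param df data.frame with the columns described in [read_metadata()].
#' @return the validated data.frame with a `paired` logical column.
#' @export
validate_metadata <- function(df) {
  need <- c("sample_id", "patient_id", "primary_cancer", "tissue", "age",
            "gender", "prior_treatment")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  bad_cancer <- setdiff(unique(df$primary_cancer), c("lung", "breast", "colorectal"))
  if (length(bad_cancer)) {
    stop("unknown primary cancer type(s): ", paste(bad_cancer, collapse = ", "))
  }
  bad_tissue <- setdiff(unique(df$tissue), c("BM", "adjacent"))
  if (length(bad_tissue)) {
    stop("unknown tissue type(s): ", paste(bad_tissue, collapse = ", "))
  }
  if (any(is.na(df$age)) || !is.numeric(df$age) || any(df$age <= 0)) {
    stop("age must be present and positive for every sample (required adjustment covariate)")
  }
  bad_gender <- setdiff(unique(df$gender), c("male", "female"))
  if (length(bad_gender)) stop("unknown gender value(s): ", paste(bad_gender, collapse = ", "))
  if (is.character(df$prior_treatment)) {
    df$prior_treatment <- tolower(df$prior_treatment) %in% c("true", "yes", "1")
  }
  df$prior_treatment <- as.logical(df$prior_treatment)
  if (any(is.na(df$prior_treatment))) stop("prior_treatment must be logical")

  bm_patients <- df$patient_id[df$tissue == "BM"]
  adj_patients <- df$patient_id[df$tissue == "adjacent"]
  orphan <- setdiff(adj_patients, bm_patients)
  if (length(orphan)) {
    warning("adjacent sample(s) without a matching BM sample for patient(s): ",
            paste(orphan, collapse = ", "), "; excluded from paired contrasts")
  }
  df$paired <- df$patient_id %in% intersect(bm_patients, adj_patients)
  df
}

#' Write sample metadata to TSV
#' @param meta metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  cols <- c("sample_id", "patient_id", "primary_cancer", "tissue", "age",
            "gender", "prior_treatment")
  utils::write.table(meta[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-sample sequencing QC statistics from TSV
#'
#' Expects columns `sample_id`, `mapped_reads`, `on_target_ratio`,
#' `n_hk_detected`.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_qc_stats <- function(path) {
  if (!file.exists(path)) stop("QC stats file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "mapped_reads", "on_target_ratio", "n_hk_detected")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("QC stats missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$on_target_ratio < 0 | df$on_target_ratio > 1)) {
    stop("on_target_ratio must lie in [0, 1]")
  }
  df
}

#' Write per-sample sequencing QC statistics to TSV
#' @param stats QC stats data.frame.
#' @param path output path.
#' @export
write_qc_stats <- function(stats, path) {
  cols <- c("sample_id", "mapped_reads", "on_target_ratio", "n_hk_detected")
  utils::write.table(stats[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
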