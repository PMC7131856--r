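#' Log2-transform an nRPM matrix
#'
#' Applies `log2(nrpm + pseudocount)` elementwise. The pseudocount (default
#' 1 nRPM) keeps zeros finite, mapping nRPM 0 to log2 value 0.
#'
#' @param nm an `nrpm_matrix` or plain non-negative gene x sample matrix.
#' @param pseudocount positive offset added before taking log2.
#' @return an object of class `expression_log` with elements `log2_nrpm` and
#'   `pseudocount`.
#' @export
log_transform <- function(nm, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  mat <- if (inherits(nm, "nrpm_matrix")) nm$nrpm else as.matrix(nm)
  if (any(mat < 0)) stop("expression values must be non-negative")
  structure(list(log2_nrpm = log2(mat + pseudocount), pseudocount = pseudocount),
            class = "expression_log")
}

#' @export
print.expression_log <- function(x, ...) {
  cat("log2 expression matrix:", nrow(x$log2_nrpm), "genes x",
      ncol(x$log2_nrpm), "samples (pseudocount ", x$pseudocount, ")\n", sep = "")
  invisible(x)
}

#' Per-gene fold changes for a contrast
#'
#' The log2 fold change is the difference of group means on the log2 nRPM
#' scale (A over B). The linear-scale fold change uses the signed convention
#' `2^log2_fc` when log2_fc >= 0 and `-2^(-log2_fc)` otherwise, so that
#' |fold_change| >= 2 is equivalent to |log2_fc| >= 1.
#'
#' @param logx `expression_log` or log2 matrix.
#' @param contrast a [make_contrast()] object.
#' @return data.frame with `gene`, `log2_fc`, `fold_change`.
#' @export
fold_change <- function(logx, contrast) {
  x <- if (inherits(logx, "expression_log")) logx$log2_nrpm else logx
  lfc <- rowMeans(x[, contrast$group_a, drop = FALSE]) -
    rowMeans(x[, contrast$group_b, drop = FALSE])
  data.frame(gene = rownames(x), log2_fc = lfc,
             fold_change = ifelse(lfc >= 0, 2^lfc, -2^(-lfc)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differentially expressed genes
#'
#' A gene is a DEG iff |fold_change| >= `fc_threshold` AND p < `p_threshold`.
#' The fold-change bound is inclusive (|FC| exactly 2 qualifies); the p-value
#' bound is strict (p exactly .05 does not). A Benjamini-Hochberg adjusted
#' column `bh_q` is added for information only and plays no part in calling.
#'
#' @param table data.frame holding at least `fold_change`, `log2_fc`,
#'   `p_value`.
#' @param fc_threshold minimum |fold change| (inclusive).
#' @param p_threshold p-value bound (exclusive).
#' @return the table with `bh_q`, `is_deg` and `direction`
#'   (`"up"`/`"down"`/`"none"`) columns.
#' @export
call_degs <- function(table, fc_threshold = 2, p_threshold = 0.05) {
  table$bh_q <- stats::p.adjust(table$p_value, method = "BH")
  is_deg <- !is.na(table$p_value) &
    abs(table$fold_change) >= fc_threshold &
    table$p_value < p_threshold
  table$is_deg <- is_deg
  table$direction <- ifelse(!is_deg, "none",
                            ifelse(table$log2_fc > 0, "up", "down"))
  table
}

#' Run a full differential-expression contrast
#'
#' Combines [moderated_t()], [fold_change()] and [call_degs()] into one DEG
#' table for a contrast.
#'
#' @inheritParams moderated_t
#' @inheritParams call_degs
#' @return a DEG table data.frame: `gene`, `log2_fc`, `fold_change`, `t`,
#'   `p_value`, `df_total`, `bh_q`, `is_deg`, `direction`, `degenerate`.
#' @export
run_deg <- function(logx, contrast, fc_threshold = 2, p_threshold = 0.05,
                    d0_override = NULL) {
  mt <- moderated_t(logx, contrast, d0_override = d0_override)
  fc <- fold_change(logx, contrast)
  tab <- data.frame(gene = mt$gene, log2_fc = fc$log2_fc,
                    fold_change = fc$fold_change, t = mt$t,
                    p_value = mt$p_value, df_total = mt$df_total,
                    degenerate = mt$degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- call_degs(tab, fc_threshold, p_threshold)
  attr(tab, "d0") <- attr(mt, "d0")
  attr(tab, "s02") <- attr(mt, "s02")
  attr(tab, "contrast") <- contrast$name
  tab[, c("gene", "log2_fc", "fold_change", "t", "p_value", "df_total",
          "bh_q", "is_deg", "direction", "degenerate")]
}

#' Exact Venn partition of 2 or 3 named gene sets
#'
#' Returns every region of the Venn partition as a sorted gene list; region
#' labels join the member set names with `&` and exclusive regions are named
#' `<set>_only`. Region cardinalities always sum to the size of the union.
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return an object of class `venn_overlap`: list with `labels`, `regions`
#'   (named list of sorted gene vectors) and `counts`.
#' @export
venn_overlap <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  k <- length(sets)
  if (!k %in% c(2L, 3L)) stop("venn_overlap supports 2 or 3 sets")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  nms <- names(sets)
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, nms))
  regions <- list()
  for (mask in 1:(2^k - 1)) {
    inc <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    label <- if (sum(inc) == 1) paste0(nms[inc], "_only")
             else paste(nms[inc], collapse = "&")
    if (length(universe)) {
      sel <- apply(membership, 1, function(m) all(m[inc]) && !any(m[!inc]))
      regions[[label]] <- universe[sel]
    } else {
      regions[[label]] <- character(0)
    }
  }
  structure(list(labels = nms, regions = regions,
                 counts = vapply(regions, length, integer(1))),
            class = "venn_overlap")
}

#' @export
print.venn_overlap <- function(x, ...) {
  cat("Venn partition of", length(x$labels), "sets:\n")
  for (nm in names(x$counts)) cat(sprintf("  %-20s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classical equal-variance two-sided t-test used for per-gene group
#' comparisons in figures. Degenerate inputs with zero pooled variance give
#' t = 0, p = 1 when the means agree, and an infinite statistic with p = 0
#' (flagged) when they do not.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list with `t`, `df`, `p_value`, `flag` (`""` or
#'   `"zero_variance_separated"`).
#' @export
two_group_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (delta == 0) return(list(t = 0, df = df, p_value = 1, flag = ""))
    return(list(t = sign(delta) * Inf, df = df, p_value = 0,
                flag = "zero_variance_separated"))
  }
  tt <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, df = df, p_value = 2 * stats::pt(-abs(tt), df), flag = "")
}
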