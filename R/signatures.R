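#' Define an immune gene-class signature
#'
#' @param name signature label.
#' @param member_genes non-empty character vector of gene symbols.
#' @return object of class `signature_def`.
#' @export
signature_definition <- function(name, member_genes) {
  member_genes <- unique(as.character(member_genes))
  if (!length(member_genes)) stop("signature '", name, "' has no member genes")
  structure(list(name = name, member_genes = member_genes),
            class = "signature_def")
}

#' Default immune gene-class signatures
#'
#' The four immune classes scored in brain-metastasis profiling: checkpoint
#' pathway (PD-L1/CD274, PD-L2/PDCD1LG2, IDO1), lymphocyte infiltration,
#' TCR coexpression, and type II interferon signaling. The shipped gene
#' lists are the members named explicitly in the source profiling work; a
#' full panel may class additional genes into each group, so the lists are
#' ordinary editable objects.
#'
#' @return named list of `signature_def` objects.
#' @export
default_signatures <- function() {
  defs <- list(
    "checkpoint pathway" = c("CD274", "PDCD1LG2", "IDO1"),
    "lymphocyte infiltration" = c("PTPN7", "IL10RA", "GZMK", "CD52", "CD2",
                                  "CCR5", "CCL5"),
    "TCR coexpression" = c("GPR18", "IL7R", "CD3G", "CD3D", "CD8B"),
    "type II interferon signaling" = c("CXCL10", "CIITA", "IRF1", "PSMB9")
  )
  mapply(signature_definition, names(defs), defs, SIMPLIFY = FALSE)
}

#' Score gene-class signatures per sample
#'
#' A sample's signature score is the unweighted arithmetic mean of the log2
#' nRPM values of the signature's member genes. Signatures with no member
#' gene present in the matrix are an error naming the signature.
#'
#' @param logx `expression_log` or log2 gene x sample matrix.
#' @param sigs list of `signature_def` objects (default [default_signatures()]).
#' @return signature x sample numeric matrix.
#' @export
score_signatures <- function(logx, sigs = default_signatures()) {
  x <- if (inherits(logx, "expression_log")) logx$log2_nrpm else logx
  scores <- t(vapply(sigs, function(sig) {
    found <- intersect(sig$member_genes, rownames(x))
    if (!length(found)) {
      stop("signature '", sig$name, "' has no member genes in the matrix")
    }
    colMeans(x[found, , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(scores) <- vapply(sigs, `[[`, character(1), "name")
  colnames(scores) <- colnames(x)
  scores
}

# Jeffreys-prior penalized logistic regression (Firth). Newton iterations on
# the penalized score U*(b) = X'(y - p + h (1/2 - p)), h = hat diagonals.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    XtWXinv <- solve(XtWX)
    h <- rowSums((XW %*% XtWXinv) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    delta <- drop(XtWXinv %*% U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  se <- sqrt(diag(solve(crossprod(X * sqrt(w)))))
  list(coef = beta, se = se, converged = it < max_iter)
}

#' Covariate-adjusted association of signature scores with cancer type
#'
#' Fits one logistic regression per signature:
#' `outcome ~ score + age + gender` by maximum likelihood, where the outcome
#' is 1 for BM samples from the `case` cancer type and 0 for the `control`
#' type (samples of other types and non-BM tissue are excluded). The reported
#' p-value is the two-sided Wald test of the score coefficient.
#'
#' Complete or quasi-complete separation leaves the MLE infinite; such fits
#' are flagged `converged = FALSE` with the direction of separation reported
#' instead of a Wald p. `firth = TRUE` switches to Jeffreys-prior penalized
#' likelihood, which always yields finite estimates.
#'
#' @param scores signature x sample matrix from [score_signatures()].
#' @param meta sample metadata data.frame (see [read_metadata()]).
#' @param case cancer type coded 1.
#' @param control cancer type coded 0.
#' @param firth use Firth-penalized likelihood instead of plain MLE.
#' @param conf_level confidence level for the Wald interval.
#' @return data.frame, one row per signature: `signature`, `n`, `coef`, `se`,
#'   `p_value`, `ci_lo`, `ci_hi`, `converged`, `separation`.
#' @export
associate_signatures <- function(scores, meta, case = "lung",
                                 control = "breast", firth = FALSE,
                                 conf_level = 0.95) {
  sub <- meta[meta$tissue == "BM" & meta$primary_cancer %in% c(case, control), ]
  sub <- sub[sub$sample_id %in% colnames(scores), ]
  if (!any(sub$primary_cancer == case) || !any(sub$primary_cancer == control))
    stop("need at least one sample per outcome level")
  y <- as.integer(sub$primary_cancer == case)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)

  res <- lapply(rownames(scores), function(sig) {
    dat <- data.frame(y = y, score = scores[sig, sub$sample_id],
                      age = sub$age,
                      gender = as.integer(sub$gender == "male"))
    if (firth) {
      X <- cbind(1, dat$score, dat$age, dat$gender)
      fit <- firth_logistic(X, dat$y)
      coef <- fit$coef[2]; se <- fit$se[2]
      z <- coef / se
      return(data.frame(signature = sig, n = nrow(dat), coef = coef, se = se,
                        p_value = 2 * stats::pnorm(-abs(z)),
                        ci_lo = coef - zq * se, ci_hi = coef + zq * se,
                        converged = fit$converged, separation = "",
                        stringsAsFactors = FALSE))
    }
    fit <- withCallingHandlers(
      stats::glm(y ~ score + age + gender, family = stats::binomial(), data = dat),
      warning = function(w) invokeRestart("muffleWarning")
    )
    coef <- stats::coef(fit)["score"]
    if (is.na(coef)) {
      # constant score carries no information: aliased coefficient
      return(data.frame(signature = sig, n = nrow(dat), coef = 0, se = Inf,
                        p_value = 1, ci_lo = -Inf, ci_hi = Inf,
                        converged = TRUE, separation = "",
                        stringsAsFactors = FALSE))
    }
    se <- sqrt(diag(stats::vcov(fit)))["score"]
    # an MLE diverging to +/-Inf (separation) shows up as an exploding
    # coefficient and/or Wald standard error
    separated <- is.finite(se) && (abs(coef) > 15 || se > 50)
    ok <- fit$converged && !separated && is.finite(se)
    z <- coef / se
    data.frame(signature = sig, n = nrow(dat), coef = unname(coef),
               se = unname(se),
               p_value = if (ok) unname(2 * stats::pnorm(-abs(z))) else NA_real_,
               ci_lo = unname(coef - zq * se), ci_hi = unname(coef + zq * se),
               converged = ok,
               separation = if (separated)
                 if (coef > 0) "higher score predicts case" else
                   "higher score predicts control" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' PCA embedding of samples on a gene subset
#'
#' Principal components of the gene-centered (optionally unit-scaled) log2
#' expression matrix restricted to a gene set. Components are ordered by
#' variance and each component's sign is fixed so its largest-magnitude gene
#' loading is positive, making coordinates reproducible.
#'
#' @param logx `expression_log` or log2 matrix.
#' @param genes genes to embed on (default all rows).
#' @param n_comp number of components to return.
#' @param scale. scale genes to unit variance before decomposition.
#' @return list with `coords` (sample x n_comp data.frame), `var_explained`
#'   (fractions), and `loadings`.
#' @export
pca_embedding <- function(logx, genes = NULL, n_comp = 2, scale. = FALSE) {
  x <- if (inherits(logx, "expression_log")) logx$log2_nrpm else logx
  if (!is.null(genes)) {
    found <- intersect(genes, rownames(x))
    if (length(found) < 2) stop("need at least 2 genes present for PCA")
    x <- x[found, , drop = FALSE]
  }
  if (ncol(x) < 3) stop("need at least 3 samples for PCA")
  if (nrow(x) < 2) stop("need at least 2 genes for PCA")
  centered <- x - rowMeans(x)
  if (max(abs(centered)) < 1e-12)
    stop("rank-deficient input: all sample profiles identical")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = scale.)
  n_comp <- min(n_comp, ncol(pc$x))
  for (j in seq_len(n_comp)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) {
      pc$rotation[, j] <- -load
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- as.data.frame(pc$x[, seq_len(n_comp), drop = FALSE])
  coords <- cbind(sample_id = rownames(coords), coords, row.names = NULL)
  list(coords = coords, var_explained = ve[seq_len(n_comp)],
       loadings = pc$rotation[, seq_len(n_comp), drop = FALSE])
}
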