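# Empirical-Bayes machinery for the moderated t-statistic.
#
# Per-gene residual variances s2_g on dg degrees of freedom are modelled as
# scaled chi-square draws around a common prior variance s0^2 with d0 prior
# degrees of freedom. (d0, s0^2) are estimated by moment-matching the log
# sample variances to a scaled F distribution (digamma/trigamma inversion),
# and each gene's variance is shrunk to
#   s2_post = (d0 * s0^2 + dg * s2_g) / (d0 + dg),
# giving t = coef / sqrt(s2_post * v) on d0 + dg degrees of freedom.

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone convex).
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (-dif / x < 1e-12) break
  }
  x
}

# Moment-match log sample variances to log of a scaled F: returns the prior
# df d0 and prior variance s02. Variances of exactly zero (constant genes)
# must be excluded by the caller.
fit_variance_prior <- function(s2, dg) {
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / max(length(e) - 1, 1)
  evar <- evar - trigamma(dg / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

#' Define a differential-expression contrast
#'
#' Two designs are supported. `unpaired` compares the mean of group A against
#' group B across independent samples. `paired` compares matched samples
#' within patients: each pair contributes one within-patient difference
#' (A minus B), tested against zero.
#'
#' @param name label for the contrast.
#' @param design `"paired"` or `"unpaired"`.
#' @param group_a,group_b character vectors of sample ids. For a paired
#'   design these must be the same length with `group_a[i]` and `group_b[i]`
#'   matched (same patient).
#' @param pairing optional character vector of patient ids, one per pair,
#'   recorded for provenance.
#' @return an object of class `contrast`.
#' @export
make_contrast <- function(name, design = c("unpaired", "paired"),
                          group_a, group_b, pairing = NULL) {
  design <- match.arg(design)
  group_a <- as.character(group_a)
  group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b)))
    stop("contrast groups must be disjoint")
  if (design == "paired") {
    if (length(group_a) != length(group_b))
      stop("paired design requires equal group sizes with matched ordering")
    if (length(group_a) < 2) stop("paired design requires at least 2 pairs")
  } else {
    if (length(group_a) < 2 || length(group_b) < 2)
      stop("unpaired design requires at least 2 samples per group")
  }
  structure(list(name = name, design = design, group_a = group_a,
                 group_b = group_b, pairing = pairing),
            class = "contrast")
}

#' Moderated t-statistics for one contrast
#'
#' Fits the per-gene linear model implied by the contrast (within-patient
#' differences tested against zero for paired designs; two-group pooled-
#' variance mean difference for unpaired), shrinks the per-gene residual
#' variances toward a common prior by empirical Bayes, and returns moderated
#' t-statistics with two-sided p-values on `d0 + dg` degrees of freedom.
#'
#' Genes whose residual variance is exactly zero are excluded from the
#' hyperparameter estimation and returned with `NA` statistics and
#' `degenerate = TRUE`. When the prior degrees of freedom estimate as
#' infinite they are capped at `d0_cap` (full shrinkage to the prior
#' variance); `d0_override = 0` disables shrinkage entirely and reproduces
#' the ordinary per-gene t-test.
#'
#' @param logx gene x sample matrix of log2 expression (see
#'   [log_transform()]), or an `expression_log` object.
#' @param contrast a [make_contrast()] object.
#' @param d0_override optional fixed prior degrees of freedom (0 = ordinary t).
#' @param d0_cap ceiling representing an infinite prior df.
#' @return data.frame with columns `gene`, `coef` (log2 scale), `t`,
#'   `p_value`, `df_total`, `s2`, `s2_post`, `degenerate`, plus attributes
#'   `d0` and `s02`.
#' @export
moderated_t <- function(logx, contrast, d0_override = NULL, d0_cap = 1e6) {
  x <- if (inherits(logx, "expression_log")) logx$log2_nrpm else logx
  stopifnot(inherits(contrast, "contrast"))
  miss <- setdiff(c(contrast$group_a, contrast$group_b), colnames(x))
  if (length(miss)) stop("samples absent from matrix: ", paste(miss, collapse = ", "))

  if (contrast$design == "paired") {
    d <- x[, contrast$group_a, drop = FALSE] - x[, contrast$group_b, drop = FALSE]
    n <- ncol(d)
    coef <- rowMeans(d)
    s2 <- apply(d, 1, stats::var)
    dg <- n - 1
    v <- 1 / n
  } else {
    a <- x[, contrast$group_a, drop = FALSE]
    b <- x[, contrast$group_b, drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    coef <- rowMeans(a) - rowMeans(b)
    ssa <- apply(a, 1, stats::var) * (na - 1)
    ssb <- apply(b, 1, stats::var) * (nb - 1)
    dg <- na + nb - 2
    s2 <- (ssa + ssb) / dg
    v <- 1 / na + 1 / nb
  }

  degenerate <- s2 <= 0 | !is.finite(s2)
  if (all(degenerate)) stop("all genes have zero residual variance in this contrast")

  if (is.null(d0_override)) {
    prior <- fit_variance_prior(s2[!degenerate], dg)
    d0 <- prior$d0
    s02 <- prior$s02
  } else {
    d0 <- d0_override
    s02 <- if (d0_override > 0) fit_variance_prior(s2[!degenerate], dg)$s02 else 0
  }
  d0 <- min(d0, d0_cap)

  s2_post <- (d0 * s02 + dg * s2) / (d0 + dg)
  tstat <- coef / sqrt(s2_post * v)
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  tstat[degenerate] <- NA_real_
  p[degenerate] <- NA_real_

  out <- data.frame(gene = rownames(x), coef = coef, t = tstat, p_value = p,
                    df_total = df_total, s2 = s2, s2_post = s2_post,
                    degenerate = degenerate, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "contrast") <- contrast$name
  out
}
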