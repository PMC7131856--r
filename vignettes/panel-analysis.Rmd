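---
title: "Immune-oncology panel analysis: models, normalization and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune-oncology panel analysis: models, normalization and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`immunopanel` analyses targeted immune-oncology RNA expression panels of the
kind used to profile the tumor immune microenvironment of brain metastases:
a ~398-plex amplicon assay measuring 395 genes (housekeeping genes included
among them — the package treats "housekeeping" as one of the eight
functional categories inside the gene universe) on FFPE tissue, with one
no-template control (NTC) library per run. The pipeline covers sequencing
QC gating, normalization to nRPM units, differential expression with an
empirical-Bayes moderated t-statistic, co-regulation overlaps, immune
gene-class signature scores, and their covariate-adjusted association with
the primary cancer type.

```{r setup}
library(immunopanel)
```

# Quality control gate

A sample enters the analysis only if all three sequencing criteria hold:

* mapped reads ≥ 200,000 (inclusive),
* on-target ratio > 50% (strict: exactly 50.0% fails),
* detected housekeeping genes ≥ 6 (inclusive).

`qc_gate()` always returns a verdict, never an error, and enumerates every
failed criterion so a sample excluded for two reasons reports both. The
boundary conventions above are fixed; the thresholds themselves are
arguments for sensitivity analyses.

# Normalization model

Counts are normalized in three steps, implemented exactly as stated and in
this order:

1. **Background subtraction.** For gene $g$ and sample $s$,
   $c^{bg}_{gs} = \max(c_{gs} - \mathrm{ntc}_g,\ 0)$. The clamp at zero is a
   deliberate choice: the assay's background estimate can exceed a low
   clinical count, and nRPM must stay non-negative for the log transform.
2. **Housekeeping ratios.** Each of the (typically 10) housekeeping genes
   has a baseline RPM profile value established from replicate runs of a
   reference cell line. The ratio uses the *absolute* (pre-subtraction)
   HK readout: $r_{hs} = c_{hs} / \mathrm{baseline}_h$. An HK gene with
   zero counts contributes a ratio of 0 — the QC gate's ≥ 6 detected-HK
   criterion is the intended guard against samples where that distorts the
   calibration.
3. **nRPM.** The per-sample normalization ratio is the median of the HK
   ratios (even counts use the midpoint convention), and
   $\mathrm{nRPM}_{gs} = c^{bg}_{gs} / \mathrm{median}_h(r_{hs})$.
   A sample whose normalization ratio is zero cannot be normalized and is
   excluded with a warning.

Because both the HK ratios and the background-subtracted counts scale
linearly with sequencing depth (the NTC is depth-independent), the nRPM
vector of a sample is invariant to rescaling its library — the property the
test suite checks to 1e-12. The baseline HK RPM profile is a required input
of the panel definition, not recomputed: the reference replicate runs that
define it are an upstream artifact of the assay.

# Log transform and differential expression

All expression-level analysis happens on $\log_2(\mathrm{nRPM} + 1)$. The
pseudocount of 1 nRPM (configurable) maps zeros to zero and is small
relative to typical signals (hundreds of nRPM).

## Moderated t-statistic

Per-gene variances at n = 10 or fewer pairs are unstable, so the package
uses the standard empirical-Bayes moderation: per-gene residual variances
$s_g^2$ on $d_g$ degrees of freedom are modelled as scaled-$\chi^2$ draws
around a prior variance $s_0^2$ with $d_0$ degrees of freedom, giving the
posterior variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
\qquad \tilde t_g = \frac{\hat\beta_g}{\tilde s_g \sqrt{v_g}}$$

on $d_0 + d_g$ degrees of freedom. $(d_0, s_0^2)$ are estimated by
moment-matching the log sample variances to a log scaled-F distribution
(digamma mean equation, trigamma variance equation inverted by Newton
iteration). This estimator is written in this package and cross-checked in
the test suite against the independent `limma` implementation to 1e-8.

Numerical conventions:

* $d_0 = \infty$ (all genes share a variance) is represented by a cap of
  1e6; `d0_override = 0` disables shrinkage and reproduces the classical
  per-gene t-test exactly, which the tests verify to 1e-10.
* Genes with zero residual variance in a contrast are excluded from
  hyperparameter estimation and reported with `NA` statistics and a
  `degenerate` flag, since a single degenerate variance poisons the
  log-moment estimation.
* Paired designs (BM vs adjacent tissue within patients) are fitted as a
  one-sample test on within-patient differences — algebraically identical
  to a patient-blocked linear model for the statistic, and strictly more
  powerful than an unpaired comparison when patients carry shared
  intercepts. Unpaired designs use the pooled two-group variance.

## DEG calling

A gene is differentially expressed iff $|FC| \ge 2$ **and** $p < .05$, with
the fold-change bound inclusive and the p-value bound strict. Fold change
is computed on the log2 scale as the difference of group means and reported
with the signed convention $FC = 2^{\Delta}$ for $\Delta \ge 0$ and
$-2^{-\Delta}$ otherwise, so $|FC| \ge 2 \iff |\Delta| \ge 1$. No multiple
testing correction enters the call — the rule is a raw-p rule by design —
but a Benjamini–Hochberg column is emitted alongside for information.

## Overlaps

Co-regulation across contrasts is summarized as the exact 2- or 3-set Venn
partition with deterministic lexicographic ordering inside regions; region
cardinalities always sum to the union (verified against brute-force
membership enumeration on random set triples).

# Signatures and association

A gene-class signature score is the unweighted mean of the member genes'
log2 nRPM values per sample. Four classes ship as defaults (checkpoint
pathway; lymphocyte infiltration; TCR coexpression; type II interferon
signaling) with the canonical member genes of each; the lists are plain
objects and a larger panel classification can replace them.

The association of each signature with the primary cancer type is one
logistic regression per signature —
`outcome ~ score + age + gender` — by plain maximum likelihood, with a
two-sided Wald p for the score coefficient. With ~18–25 samples and strong
class shifts, quasi-complete separation is the expected failure mode: the
package flags such fits (`converged = FALSE`, with the direction of
separation) rather than report an unstable Wald p, and offers a
Firth/Jeffreys-penalized fit behind `firth = TRUE` for users who want
finite estimates under separation. Gender enters as a single indicator and
age in years untransformed; the covariate-invariance properties (gender
relabeling, affine age rescaling) are part of the test suite.

PCA sample embeddings are computed on the gene-centered (optionally
unit-scaled) log2 matrix; components are ordered by variance and signs are
fixed so each component's largest-magnitude loading is positive, making
coordinates reproducible across platforms.

# The synthetic-data generator

`sim_config()` / `simulate_counts()` generate complete study data sets so
every pipeline stage is testable without any external download. The model:

* per-gene baseline log2 expression ~ Normal(8, 2) on the log2-count scale
  (counts of ~256 at a typical per-sample total near 300k reads, matching a
  targeted panel at roughly 1M reads per library);
* negative-binomial counts (default dispersion 0.05) with log-normal
  library-size factors (sd 0.2 on the log2 scale);
* housekeeping genes drawn around a high stable baseline (log2 mean 10,
  per-sample biological sd 0.05), with the panel's baseline RPM profile set
  to their expected reference counts so a unit-library sample has HK ratios
  near 1;
* NTC background ~ Poisson(5) per gene;
* a per-patient, per-gene random intercept (sd 0.5) shared by a patient's
  BM and adjacent samples, which makes the paired design genuinely more
  powerful than the unpaired one;
* per-sample biological noise of sd `within_pair_sd / sqrt(2)` (default
  `within_pair_sd = 0.5`, the standard deviation of a paired log2
  difference);
* planted effects: explicit per-gene log2 shifts in designated
  (cancer, tissue) groups, and per-class mean shifts for signature
  analyses. Everything planted is exported in a truth record so validation
  code never reaches into generator internals.

The default cohort is 12 lung, 6 breast and 7 colorectal patients with
10 + 3 paired adjacent-tissue samples — 38 libraries plus the NTC.

What the generator does *not* emulate: FFPE degradation gradients, run- or
batch-level effects beyond a scalar library size, correlated gene modules
(genes are independent given the patient intercept), amplification bias, or
sequence content. Passing tests on simulated data therefore demonstrate the
pipeline's correctness under its own model assumptions, not robustness to
every artifact of archival clinical material.

# Validation design and problem sizes

The package validates itself at these scales, chosen to give tight
statistical bands while keeping the full suite around a quarter of a
minute:

* normalization against an independently coded oracle on 20 random
  395 × 10 count matrices (exact equality);
* null calibration of the moderated t on 50 replicates of 200 genes ×
  2×5 samples, with per-gene variances drawn from a scaled chi-square —
  the hierarchical regime the statistic is built for; with strictly equal
  variances the statistic is mildly conservative (shrinkage is total and
  the shared prior-variance estimate correlates genes), which the unit
  suite covers separately with a slack band;
* planted-effect recovery at 20 genes of |log2 effect| 2, 10 pairs,
  within-pair sd 0.5 and near-zero count dispersion (the condition the
  recovery claim is stated for), requiring ≥ 90% sensitivity and ≤ 7%
  false-positive rate;
* logistic recovery at n = 500 with a true score log-odds of 1.0 over 200
  replicates (bias within ±0.2, CI coverage ≥ 93%);
* the generator's own null: 50 full cohorts with no planted effects, where
  the paired-contrast p-values stay in the 99% binomial band around 5%.

# Known limitations

* The housekeeping-ratio scheme corrects a scalar per-sample factor only;
  gene-specific efficiency differences between runs are out of scope.
* The DEG rule uses raw p-values by construction; at 395 genes a handful of
  null genes passing p < .05 is expected, and the |FC| ≥ 2 requirement is
  what keeps the realized false-positive rate low.
* Plain-MLE logistic association is fragile at small n with strong
  signatures; the separation flag (and optional Firth fit) make this
  explicit rather than hiding it.
* Signature gene lists ship as the canonical published members of each
  class; a full panel's class assignment may be larger, and scores change
  accordingly.
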