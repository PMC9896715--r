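---
title: "Methods: per-patient differential expression, DEPC aggregation and patient stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-patient differential expression, DEPC aggregation and patient stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the choices
made where the design was genuinely open. It states no empirical result
that the test suite does not itself compute.

## 1. The statistical model

### Counts and normalization

Raw counts $y_{gs}$ for gene $g$ in sample $s$ are modelled as negative
binomial with mean $\mu_{gs} = q_{gs}\, c_s$ and variance
$\mu_{gs} + \alpha_g \mu_{gs}^2$, where $c_s$ is a sample-specific size
factor and $\alpha_g$ a gene-specific dispersion. Size factors use the
median-of-ratios estimator: $c_s = \operatorname{median}_g\,
y_{gs} / (\prod_{s'} y_{gs'})^{1/n}$ over genes whose geometric mean is
positive. Matrices where no gene is expressed in every sample raise an
error pointing at the `pseudo_reference` fallback (geometric means over
positive entries only) rather than silently switching estimators.

Two further transforms are provided because different stages consume
different scales: `mor_log2()` ($\log_2(y/c + 1)$) for display and general
use, and `tmm_cpm_log()` ($\log_2(\mathrm{CPM} + 0.5)$ on effective library
sizes from a trimmed-mean-of-M-values factor: 30% two-sided trim on
M-values, 5% on A-values, precision-weighted mean, factors normalized to
geometric mean 1, reference sample chosen by upper-quartile closeness to
the mean upper-quartile) for the classifier features. The TMM factor is an
independent reimplementation and is cross-checked against edgeR in the test
suite; a variance-stabilizing transform is deliberately replaced by the
shifted log (`shifted_log()`) since it is only ever used for display.

### Filtering

`filter_genes()` keeps genes with at least 1 count in at least
$\lceil 0.3\,n \rceil$ samples. Filtering is applied once, globally, before
all analyses; applying it per analysis instead is possible by calling it on
subsets, and the choice is exposed rather than hidden because the two
conventions give slightly different per-patient universes.

### Dispersion estimation

With only 3–6 samples per patient, gene-wise dispersion estimation is
hopeless; the engine therefore mirrors the information-sharing *role* of
the established shrinkage estimators without cloning them:

1. gene-wise method-of-moments estimates on normalized counts, floored at
   $10^{-8}$;
2. a parametric trend $\alpha(\mu) = a_0 + a_1/\mu$ fitted by an iterated
   Gamma GLM with outlier exclusion (ratio outside $[10^{-4}, 15]$);
3. the final value $\exp\{w \log \alpha_{\text{trend}} +
   (1-w)\log \alpha_{\text{gene}}\}$ with $w = 0.5$ by default, forced to
   $w = 1$ when the residual degrees of freedom are $\le 1$ — which is why
   per-patient fits always use the pure trend.

### Wald testing and calls

Per gene, a log-link NB GLM with offsets $\log c_s$ is fitted by Fisher
scoring (IRLS weights $\mu/(1+\alpha\mu)$, compiled in C++). The reported
effect is a design contrast divided by $\ln 2$, its standard error comes
from the inverse Fisher information, and the two-sided normal tail gives
the Wald p-value, clipped to $[10^{-300}, 1]$. Non-converged genes are
flagged and set to $p = 1$. BH adjustment runs within each DE run
independently (per patient, per design), matching how such analyses are
invoked in practice. Calls: up iff $p_{\text{adj}} < 0.05$ and
$\log_2\mathrm{FC} > 1$; down symmetric.

Fold-change shrinkage priors (apeglm/ashr style) are *not* reimplemented —
they are substantial standalone methods; the decision rule operates on the
unshrunk MLE, and an optional ridge prior (Normal(0, 4) on the log2
coefficient) is available behind the `ridge` argument for users who want
stabilized small-sample estimates.

### The three designs

* all-patients: `~ patient + sample_type`, testing the tumour coefficient;
* per-patient: `~ sample_type` on one patient's samples (requires ≥ 2
  tumour regions and exactly 1 normal; others are skipped with a warning);
* between-groups: intercept, group main effect, within-group renumbered
  patient offsets and one tumour effect per group, built explicitly as
  dummy columns (R's formula expansion aliases nested factors), testing
  the difference of the two tumour effects.

## 2. DEPC, AP/NAP and the threshold universe

DEPC of a gene is the number of patients calling it up (down counted
separately). The selection threshold is $\bar d + 2\,\mathrm{sd}(d)$,
inclusive. The open design question is which gene universe enters the mean
and SD. We default to **all genes in the analysed matrix (zeros
included)**, with `"nonzero"` available. Rationale: with an FDR-controlled
per-patient engine the nonzero universe is small and dominated by the
highly shared genes themselves, so the threshold lands above every
subgroup-shared gene and selects nothing but cohort-wide genes — the
statistic stops measuring what it is meant to measure. Over the full
universe the threshold falls between the sporadic-call floor and the
subgroup-shared stratum, which is also the regime in which the published
thresholds of this workflow (27/34 in a 90-patient cohort, with
subgroup-specific genes above them) must have lived.

## 3. The synthetic cohort: what it emulates and what it does not

Defaults (chosen once; all overridable in `sim_config()`):

* 90 patients, one adjacent normal each, 2–5 tumour regions uniform;
* 2000 genes: 1% CORE_UP (+2 log2 in every tumour), 1% CORE_DOWN (−2),
  5% SUBGROUP_UP (+2 only in tumours of the gene's target group, drawn
  uniformly), 93% null. The cohort-wide classes are kept deliberately
  small: in this scaled 2000-gene world the DEPC threshold arithmetic only
  reproduces the published regime (threshold between noise floor and
  subgroup stratum) when the point mass of cohort-wide genes does not
  dominate the DEPC variance;
* baseline $\log$-mean $\sim N(5, 1.2^2)$ (median ≈ 150 counts);
  between-patient baseline SD 0.2 (natural log), 0.9 for SUBGROUP_UP genes
  — the high-variance stratum that makes the cohort-level analysis miss
  them;
* NB dispersion 0.05, library factors log-normal (SD 0.25);
* 3 latent groups with membership probabilities (0.47, 0.40, 0.13),
  approximating the published 42/36/12 split; exponential recurrence with
  hazards 1/1000, 1/400, 1/700 per day and administrative censoring at
  1825 days (5 years) — medians of roughly 1.9/0.8/1.3 years with the
  up-regulation-rich group recurring fastest.

The generator does **not** emulate: read-level artefacts, isoforms,
GC/length bias, clonal phylogenies across regions, or — importantly —
*patient-private* dysregulation (real tumours carry on the order of a
thousand private DE genes per patient). A green planted-recovery test
therefore establishes that the pipeline recovers the modelled subgroup
structure, not that it would behave identically on data with heavy private
signal; the pairing-permutation comparison is the one stage where this gap
is visible (the permuted analyses dominate the low-DEPC band here, whereas
with large private mass the correct pairing does).

## 4. Co-clustering

`blockcluster`-style variational inference is replaced by a classification
EM on the categorical latent block model: hard row/column assignments
maximizing the complete-data log-likelihood alternate with smoothed
parameter updates ($\theta_{k\ell}$ with pseudo-count 0.5 per category —
avoiding $\log 0$ on pure blocks; mixing proportions smoothed likewise).
The traced objective includes the smoothing prior terms, so it is provably
non-decreasing within a restart; 20 random restarts with derived seeds make
the fit deterministic given `seed`. Empty clusters are reseeded with the
worst-fitting row/column. CEM yields hard partitions directly, which is all
the downstream stages consume. The gene-side cluster count is not part of
any contract; it defaults to 3 symmetric with the patient side.

Group labels are canonical: patient clusters sorted by ascending mean
number of +1 cells, so the up-regulation-rich cluster is always the
highest-numbered PG regardless of the fit's arbitrary numbering.

## 5. Survival testing

The weighted log-rank statistic uses weights 1 (log-rank), the
left-continuous pooled Kaplan–Meier $\tilde S(t-)$ (Peto-Peto; verified to
machine precision against `survival::survdiff(rho = 1)`), or
$\tilde S(t-)\, n/(n+1)$ (modified Peto-Peto, the default). The exact
convention behind the "modified" name is not universal; both variants are
exposed. A known consequence of the early-event weighting, measured by the
test suite: under proportional hazards at hazard ratio 2 with 40 patients
per group, its power is ≈ 0.74 where the unweighted log-rank reaches
≈ 0.87 — a real property of the test, not an implementation artefact.

Clinical association screens use Fisher's exact test when any expected cell
is below 5 (Monte Carlo with plus-one correction for tables beyond 2×2)
and Pearson's chi-square otherwise; continuous covariates use the
two-sided Wilcoxon rank-sum test (exact enumeration when the pooled sample
is ≤ 12 without ties). One-sided Wilcoxon directions must always be passed
explicitly — no silent defaults.

## 6. Classifier

TND instances (tumour minus patient-normal on the TMM-CPM-log scale) are
classified by an MLP with four linear layers (defaults 200/100/50 hidden;
widths are not dictated by any contract and merely taper from the feature
dimension), ReLU activations with Kaiming-normal initialization on the
first three, Xavier-uniform and softmax on the output, SGD (lr 0.01,
momentum 0.9), cross-entropy, 500 epochs, batch 32, 7:3 instance-level
splits, 1000 trials. Instance-level splitting means one patient's regions
may straddle train and test; `split_by_patient = TRUE` exists for users
who consider that leakage. Per-instance label counts over trials are
tested against the uniform expectation (trials/k per group) by chi-square
goodness of fit; BH across instances; significant instances take the label
with the largest standardized residual (ties to the lowest group index),
others remain unassigned. No class reweighting is applied.

## 7. Numerical choices and degenerate inputs

* IRLS: linear predictor clamped to ±30, convergence at relative
  coefficient change $< 10^{-8}$, max 50 iterations, singular information
  matrices fall back to a pseudo-inverse or flag the gene.
* All Monte-Carlo and ensemble stages take explicit seeds; the pipeline
  derives per-stage seeds from one global seed by fixed offsets.
* Zero-variance survival comparisons (no events) return $p = 1$ with a
  warning rather than NaN.
* All-zero DEPC input is an error (no informative genes), not a threshold
  of 0.

## 8. Known limitations

* No Cox regression or multivariable survival modelling; no model
  selection over the number of patient groups (fixed, default 3).
* No independent filtering, outlier refitting, or fold-change shrinkage in
  the DE engine; p-values with 3–6 samples lean on the dispersion trend
  being roughly right.
* The MLP is CPU-only by design; wall-clock scales linearly in trials.
* Enrichment is over-representation only; no rank-based statistic.
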