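---
title: "Detecting differential isoform ratios between tumor cohorts"
author: "isoratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential isoform ratios between tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoratio)
```

## The problem

A gene's transcript isoforms can shift in relative abundance between two
tumor states — say primary versus metastatic melanoma — even when total
gene expression does not change. Such *differential isoform ratio* (DIR)
events are invisible to standard differential-expression analysis, but
they can remodel protein domains (kinases are a prime example: splicing
can delete a localization or interaction domain while leaving the
catalytic core intact). `isoratio` implements a testing and validation
stack for DIR between two cohorts of isoform-level abundance estimates
(TPM scale, e.g. kallisto output), together with a synthetic cohort
generator so that every stage can be validated against known ground
truth without access to protected patient data.

## The DIR models

For each gene with $n \ge 2$ isoforms, the per-sample isoform
abundances are collected into a vector and normalized to sum to 1
(samples with zero counts across all isoforms are dropped — they carry
no ratio information). Two models test whether these ratio vectors
differ between the groups.

**Permutation/LDA model.** Fisher's linear discriminant reduces the
ratio vectors to the one-dimensional axis that best separates the two
groups, and the separation statistic

$$ S = \frac{(\mu_1 - \mu_2)^2}{\sigma_1^2 + \sigma_2^2} $$

is computed from the projected group means and (unbiased) variances.
Group labels are then permuted and the *entire fit* — discriminant
direction and statistic — recomputed each time. The p-value is
$(1 + b)/(n_{\mathrm{iter}} + 1)$, where $b$ counts permuted statistics
at least as large as the observed one; this is valid by construction and
makes the resolution floor $1/(n_{\mathrm{iter}}+1)$ explicit. When the
number of distinct labelings is at most $n_{\mathrm{iter}}$ the test
enumerates all of them and the p-value is exact. Two numerical choices
deserve note:

* The sum-to-one constraint makes the ratio space rank-deficient, so
  the coordinate with the smallest overall variance is dropped before
  fitting and the pooled within-group covariance is pseudo-inverted
  (`MASS::ginv`). This also keeps genes with more isoforms than samples
  projectable.
* If the within-group scatter vanishes entirely, the projection falls
  back to the mean-difference axis; a zero denominator yields $S = 0$
  for equal means and $S = \infty$ otherwise.

Refitting the direction inside every permutation is the conservative
reading of "recompute the statistic"; a frozen-direction variant would
anti-conservatively reuse information from the observed labeling.

**PCA model family.** The permutation test's cost and resolution floor
make it awkward for thousands of genes, so a faster family is built on
principal components of the ratio space (mean-centered, unscaled).
Components with variance below $10^{-12}$ times the leading variance
are dropped; the simplex constraint forces at least one such component,
leaving at most $n-1$ components for $n$ isoforms. Along each retained
component two tests are run: Welch's t-test and the two-sample general
independence test (the conditional-inference linear statistic
$T=\sum_{i \in \text{group 1}} x_i$ standardized by its exact
permutation moments, referred to the normal). Each family's
per-component p-values are combined with Fisher's method
($-2\sum\ln p \sim \chi^2_{2m}$), and the two family p-values are
merged by their geometric mean:

$$ p_{\mathrm{geo}} = \sqrt{p_{t\text{-Fisher}} \cdot p_{\mathrm{coin\text{-}Fisher}}}. $$

The geometric mean is *not* a calibrated p-value under the null — it is
anti-conservative relative to its factors — but it tracks the
permutation reference better than either factor alone, which is exactly
how it is used: as a ranking statistic that is then
Benjamini–Hochberg-adjusted across genes, with the calibrated
permutation model available for confirmation. The harmonic-mean
combiner (`hmp_combine`) is provided for the model-comparison harness:
it evaluates the asymptotically exact tail of the Landau distribution
(location $\log m + 1 - \gamma$, scale $\pi/2$) for the mean of $m$
reciprocal uniform p-values, via the exact integral representation
$\frac{1}{\pi}\int_0^\infty e^{-t\log t - (x-\mu)t}\,\frac{\sin \pi t}{t}\,dt$,
which is non-oscillatory for every argument (a substitution $u=(x-\mu)t$
keeps it well-scaled deep in the tail). Zero p-values are clamped at
machine epsilon before any log or reciprocal transform.

`compare_tests` quantifies agreement of any candidate against the
permutation reference by Pearson/Spearman correlations (raw, rank and
log scale) and Youden's J ($\text{sens} + \text{spec} - 1$) at
$\alpha \in \{0.05, 0.01, 0.001\}$, treating reference calls as ground
truth.

## Sample quality control

Two per-sample filters precede testing, with the boundary semantics
applied literally: samples are removed when consensus purity is
*strictly below* 0.70 or when the 3' bias score is *strictly above*
0.55 — the boundary values themselves are retained. A sample missing
the score for an active filter is excluded (reason `"missing"`); the
conservative choice, since consensus purity tables rarely cover every
sample. Either filter can be disabled with `NA`.
`sample_removal_sensitivity` implements the one-by-one removal
diagnostic: a DIR signal that evaporates quickly when the
highest-bias (or lowest-purity) samples are removed first — but not
under the reverse ordering — was likely driven by those samples.

## Per-sample clustering of metastatic samples

Each metastatic sample is compared with the whole primary pool, per
isoform, by a quasi-Poisson GLM with a group indicator. With one
observation in the metastatic "group" the model is saturated, so the
fit is closed-form: fitted means are the group means, the dispersion is
Pearson $X^2/(N-2)$ (falling back to 1 only when $X^2$ is exactly 0),
and the indicator coefficient gets a two-sided Wald t-test with $N-2$
degrees of freedom. Quasi-likelihood needs no integrality, so TPM
values enter as-is. A fitted group mean of zero lies on the boundary of
the log-link space; it is floored at half a count (0.5), which keeps
the coefficient and standard error finite — the same effect a bounded
IRLS would have, without the iteration.

Calls are digitized asymmetrically: $+1$ for increases at $p < 0.05$,
$-1$ for decreases at the liberal $p < 0.20$, else 0. Low-count
Poisson-like data can rarely attain strong downward significance in a
single sample, so a symmetric threshold would miss almost all
down-regulation. Isoforms altered in strictly more than 13% of samples
are retained, and the ternary matrix is biclustered by Euclidean
k-means (10 restarts, seeded) on both axes. The number of clusters is
chosen at the elbow of the within-cluster sum-of-squares curve,
operationalized as the largest second difference; a manual override is
supported because elbow calls on real data are sometimes adjusted by
inspection (e.g. increasing the isoform-group count by one to sharpen
enrichment patterns). Cluster–metadata associations (region, genomic
subtype, batch, kinase group) use one-sided Fisher exact tests, with
sample odds ratios (0.5 added to all cells only when one is zero).
Immune-infiltrate samples are identified by 2-center k-means on the
digitized profiles restricted to an immune isoform program, labeling
the cluster with the higher up-call rate.

## Junction-level validation

Isoform quantifiers can be misled by 3' degradation bias; split reads
over exon–exon junctions are direct evidence. For a skipped exon the
per-sample event fraction is
$\mathrm{skip} / (\mathrm{skip} + (\mathrm{flank}_L + \mathrm{flank}_R)/2)$;
two-way events (alternative promoter, mutually exclusive or terminal
exons — structurally identical two-junction choices) use
$a/(a+b)$. Samples with no reads over the event are dropped, not
imputed. Groups are compared by a one-sided Wilcoxon rank-sum test in
the direction expected from the quantification result being validated.
Junction tables follow the STAR `SJ.out.tab` coordinate convention
(1-based, intron-inclusive), as a long six-column TSV keyed by sample;
junctions absent from a sample's rows count as zero, since aligners
omit unobserved junctions.

## Enrichment

Ranked gene lists (DIR or any externally produced ranking) are
thresholded at percentile cutoffs — top 5/10/20/40% with ceiling
rounding, so 538 ranked kinases give a top-5% set of 27 and 468 give
24 — which keeps foreground sizes comparable across sample sets whose
p-value scales differ. Each annotation set is tested by the one-sided
hypergeometric test against the remaining genes as background.
Enrichment p-values are deliberately left unadjusted: annotation sets
are strongly dependent and the constrained universe (every gene a
kinase) already rules out many terms, so BH correction would
misrepresent the error rate. The companion control is an *empirical*
FDR: random foregrounds of the observed size are drawn and the mean
number of sets passing the threshold is compared with the observed
count.

## The synthetic cohort generator

`generate_cohort` emulates the statistical structure of a two-cohort
isoform study, with every planted effect recorded in a truth object:

* **Isoform structure**: isoform counts per gene uniform on a
  configurable range (default 1–6); baseline proportions drawn from a
  symmetric Dirichlet.
* **Ratio switches**: in a configurable fraction of multi-isoform
  genes, mass `dir_delta` is moved from the dominant isoform to the
  runner-up in the metastatic group (the baseline is adjusted, before
  any draw, so the donor isoform has at least `dir_delta + 0.05` to
  give).
* **Proportion noise**: per-sample vectors are redrawn from a
  Dirichlet centered on the group proportions with concentration 20 by
  default — a per-sample ratio standard deviation near 0.1, typical of
  bulk tumor isoform-ratio estimates.
* **Expression**: gene totals are log-normal (baseline
  `meanlog = log 50`, `sdlog = 1` across genes, within-sample noise
  0.3), with signed log2 fold-changes applied to the metastatic group
  for the DE genes and per-batch per-gene multiplicative factors
  (log-sd `batch_sd`). The Dirichlet-times-log-normal construction
  matches the continuous TPM scale of the inputs; no negative-binomial
  read-count layer is simulated.
* **Impurity**: per-sample purity is Beta-distributed per group (a
  second shape of 0 pins purity at 1); samples are mixed linearly with
  a contaminant profile. A designated infiltrate subset of metastatic
  samples mixes with an immune program — a fixed 10% of genes boosted
  20-fold, shared across infiltrate samples, reproducing the
  correlated up-regulation block that immune infiltrate creates — while
  the remaining impure samples mix with a neutral stromal profile.
* **3' fragment bias**: half of the multi-isoform genes get their last
  isoform designated as the 3' fragment. A fraction
  $f = \text{strength} \cdot \max(0, (b - 0.4)/0.6)$ of the
  non-fragment mass moves onto the fragment isoform, conserving the
  gene total exactly. The piecewise-linear form is a modeling choice:
  it places the QC filter threshold (0.55) inside the active range, and
  only the existence and direction of the skew matter for validating
  downstream behavior.
* **Junctions**: split-read counts are Poisson around
  $\text{depth}\cdot\psi$ (inclusion flanks) and
  $\text{depth}\cdot(1-\psi)$ (skip), where $\psi$ is the sample's
  summed proportion of inclusion isoforms taken from the
  impurity-mixed but bias-free proportions — junction reads come from
  the actual RNA pool, so they see contamination but not the
  quantification artifact they are meant to expose.

One global seed is split into per-stage streams, so identical
configurations reproduce bit-identical cohorts and individual stages
stay reproducible when upstream parameters change.

What the generator does *not* emulate: read-level error, positional
coverage profiles, correlated gene–gene expression beyond the immune
block, isoform annotation error, or negative-binomial count noise.
Passing tests therefore demonstrate that the statistical machinery
recovers the effects it claims to detect under a faithful abstraction
of the data's structure — not that any particular real cohort satisfies
that abstraction.

## Worked example

```{r example}
cfg <- cohort_config(n_primary = 30, n_metastatic = 60, n_genes = 80,
                     frac_dir_genes = 0.15, dir_delta = 0.3, seed = 7)
cohort <- generate_cohort(cfg)
cohort

qc <- filter_samples(cohort$meta)
length(qc$retained)

res <- dir_test(cohort$counts, cohort$meta)
res <- res[order(res$p_geo), ]
head(res[, c("gene_id", "n_isoforms", "n_components", "p_geo", "p_adj")])

# how many planted switches are recovered at FDR 0.05?
called <- res$gene_id[!is.na(res$p_adj) & res$p_adj < 0.05]
table(planted = res$gene_id %in% names(cohort$truth$dir_genes),
      called = res$gene_id %in% called)
```

## Problem sizes used in validation

The shipped test-and-acceptance battery exercises the stack at sizes
chosen to make its statistical claims sharp while staying desk-scale:
500 null genes for calibration (permutation model at
$n_{\mathrm{iter}} = 999$), 50 genes of up to 10 samples for the
sampled-vs-exhaustive permutation cross-check at
$n_{\mathrm{iter}} = 50{,}000$, 150-gene cohorts at 50 vs 150 samples
for power over $\delta \in \{0.1, 0.2, 0.3\}$, a 40 + 60 + 60 cohort
for subgroup recovery, 100 replicates for junction detection, and every
2×2 table with $N \le 30$ for the hypergeometric oracle.

## Known limitations

* The geometric-mean p-value is uncalibrated under the null; treat
  `p_adj` as a ranking-based FDR and confirm borderline calls with the
  permutation model.
* The independence test uses the asymptotic normal reference; for very
  small groups the permutation model is the safer choice.
* The elbow rule is a formalization of a judgment call; inspect
  `wss_curve` and use the overrides when the curve is flat.
* Percentile enrichment inherits the ranking's quirks — a foreground
  defined by rank, not significance, can be dominated by noise when the
  ranking carries little signal; the empirical FDR quantifies exactly
  this.
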