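---
title: "Methods: mutual-information co-expression networks for small-RNA counts"
author: "rcmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutual-information co-expression networks for small-RNA counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcmir)
```

## Overview

`rcmir` implements a complete analysis chain for miRNA count data from a
small perturbation experiment — the motivating design is a melanoma cell
line (B16F1) exposed for 72 h to L-tyrosine or to
5-bromo-2'-deoxyuridine, three replicates per condition, profiled by
small-RNA sequencing. The chain is:

1. median-of-ratios normalization and PCA sample scores;
2. a per-miRNA negative binomial Wald test between two conditions with
   Benjamini–Hochberg correction;
3. a co-expression network over the differentially expressed miRNAs:
   equal-frequency discretization, pairwise mutual information mapped to a
   [0, 1] similarity, a data-driven similarity threshold chosen by
   comparing the network clustering coefficient with its random-graph
   expectation, and connected-component clusters;
4. cluster common-target identification against a miRNA→gene prediction
   table, with hypergeometric gene-set enrichment;
5. efficiency-adjusted qPCR relative expression ratios (rER) and the
   growth-phenotype arithmetic (percent reduction, doubling time, CV,
   linear calibration curves).

A seeded synthetic-data generator produces inputs with the statistical
structure the analysis assumes, so the whole chain is testable without any
external download.

## Normalization and differential expression

Size factors are the median, over miRNAs with positive counts in every
sample, of the ratio of a sample's count to the miRNA's geometric mean.
They are defined up to a common constant; tests and downstream code only
rely on ratios. PCA operates on the column-centred `log2(x + 1)` matrix —
the pseudo-count handles zeros and the log keeps high-abundance miRNAs
from dominating; component signs are fixed by making each component's
largest-magnitude loading positive so scores are reproducible.

The differential-expression test is a deliberately simple negative
binomial Wald test, not a reimplementation of shrinkage-based tools. For
one miRNA with normalized counts split into reference and test groups:

* effect: `log2FC = log2((mean_test + 0.5) / (mean_ref + 0.5))`. The 0.5
  pseudo-count bounds fold changes for genes with an all-zero group.
* dispersion: method-of-moments,
  `alpha = max(0, (within-group pooled variance − pooled mean) / pooled mean²)`,
  clipped at zero for under-dispersed genes.
* standard error: delta method under `Var(K) = mu + alpha mu²` per group,
  with each sample's size factor entering the Poisson term.
* reference distribution: **t with `n − 2` degrees of freedom**, not
  normal. With three replicates per group the variance estimate carries
  roughly four degrees of freedom, so the Wald ratio behaves like `t_4`;
  against a normal reference the null rejection rate at 0.05 is about
  0.12 (`P(|t_4| > 1.96) ≈ 0.116`), while the t reference brings it to
  ≈ 0.05. We verified this on 2000 simulated null genes (NB, mean 100,
  dispersion 0.1, 3 vs 3).

Because no information is shared across genes, power is lower than
shrinkage estimators achieve: with 3 vs 3 replicates and |log2FC| = 3 at
mean 500, roughly 60 % of planted effects survive BH at 0.05. That
trade-off is intrinsic — per-gene dispersion with four degrees of freedom
either inflates false positives (normal tail) or costs power (calibrated
tail); sharing dispersion across genes is precisely what DESeq2-style
shrinkage adds, and it is out of scope here. Consequently exact DE lists
from the motivating dataset are not a reproduction target.

BH adjustment wraps `stats::p.adjust(method = "BH")`; the test suite
checks it against a direct step-up enumeration on all orderings of six
p-values. The choice of BH for the otherwise unspecified
multiple-testing correction follows the field default for count-based DE
output.

## The co-expression network (RC-miR chain)

**Discretization.** Each miRNA's normalized profile across samples is cut
into `nbins` equal-frequency bins by rank quantiles
(`label = floor(rank0 · nbins / n)` on 0-based ranks). Ties are broken by
stable order of occurrence, so bin occupancies never differ by more than
one and the result is deterministic. The default bin count is
`floor(sqrt(n_samples))` with a minimum of 2 (nine samples give three
bins) — a standard small-sample rule; it is configurable because no
single value suits every design.

**Similarity.** Pairwise mutual information of the discretized profiles is
the plug-in estimator in nats. It is mapped to
`s = sqrt(1 − exp(−2 I))`, the transform under which the MI of a
bivariate Gaussian returns its absolute correlation, giving a
correlation-like similarity in [0, 1) with `s(0) = 0`. MI rather than
Pearson correlation is used because the relationships between miRNA
profiles need not be linear or even monotone.

**Threshold selection.** For each `tau` on a grid (default 0.01–0.99,
step 0.01) the similarity matrix is binarized with a *strict* inequality
`s > tau`, isolated nodes are set aside, and the gap
`d(tau) = |C(tau) − Cr(tau)|` is computed, where `C` is the
Watts–Strogatz average local clustering coefficient (nodes of degree < 2
contribute 0) and `Cr = 2m / (n(n−1))` is the Erdős–Rényi expectation for
a density-matched random graph. The selected `tau*` is the smallest grid
value, among those whose network still has an edge, whose gap strictly
exceeds the gap at the next grid point — the first local peak of
clustering above randomness. When the gap never strictly decreases (for
instance when all off-diagonal similarities are equal) the scan raises an
explicit `no_threshold` error rather than guessing; the full scan table
is always retained for inspection. Because small-sample MI takes few
distinct values, `d(tau)` is piecewise constant and the "first strict
decrease" rule fires at genuine drops, not numerical jitter.

**Clusters.** The adjacency at `tau*` (zero diagonal, symmetric) is split
into connected components; components with at least two members are
reported as clusters (ordered by size, then lexicographically by first
member), the rest as singletons. The network stage is run per contrast
and per expression block — over-expressed, under-expressed, and all DE
miRNAs — which for two exposures yields the six similarity matrices the
pipeline writes.

### Small-sample resolution limit

With nine samples and three bins the plug-in MI of two *independent*
profiles is strongly positively biased and heavily quantized: its
similarity reaches the 0.86 level (one step below the 0.943 maximum) with
probability ≈ 0.10. In a 50-node network that expectation amounts to
~100 spurious edges at any threshold low enough to keep a genuinely
co-expressed group connected, and connected components then percolate
into one giant cluster. The practical consequences, which the test suite
and the acceptance script measure rather than hide: under these
conditions a planted 6-member cluster (loading 1.0, dispersion 0.1) is
essentially never isolated exactly (best-cluster Jaccard with truth has
median ≈ 0.12 across seeds), even though its *pairwise similarities* do
exceed the background's in almost every seed. Reliable cluster recovery
needs more samples, fewer candidate nodes (e.g. restricting to a small DE
set, as the motivating study does), or an external threshold. Bias
correction of the MI estimator does not help: it shifts all pairs
monotonically and leaves every thresholded topology unchanged.

## Targets, common targets, enrichment

Prediction tables are consumed as files (TSV with configurable column
names); the prediction algorithm itself is not reimplemented. miRNA
identifiers are matched case-insensitively with the three-letter species
prefix stripped (only when it precedes a `mir`/`let` stem), bridging
miRBase and TargetScan dialects. A cluster's common targets are the
intersection of its members' target sets; a member absent from the table
empties the intersection and is flagged. Enrichment is the upper-tail
hypergeometric probability `P(X ≥ k)` per gene set, with the universe an
explicit input (results depend on it; no silent default beyond the target
table's gene space). Raw p-values below 0.05 are called significant by
default, matching the common reporting convention for this test; BH
adjustment is available but off by default.

## qPCR relative expression ratio

`rER = E_t^(ΔCt_t) / E_r^(ΔCt_r)` with `ΔCt = Ct_control − Ct_treated`,
so `rER > 1` means up-regulation in treated cells. Efficiencies must lie
in (1, 2.2]; they can be estimated from a standard-curve slope as
`E = 10^(−1/slope)`. Replicates are aggregated by pairing replicate *r*
of control with replicate *r* of treated and summarizing the per-pair
ratios as mean ± sd; averaging Ct values before taking the ratio is
available as an option (`aggregate = "mean_ct"`). At zero noise the
generator→estimator round trip is exact.

## Growth-phenotype arithmetic

Percent reduction `100 (n_c − n_t) / n_c`, population doubling time
`Δt ln 2 / ln(n2/n1)`, coefficient of variation `100 sd / mean`, the
supernatant death-to-loss ratio `(n_c − n_t) / dead`, and ordinary
least-squares calibration curves with a `3.3 σ / slope` detection limit.
Ratios and percentages are reported both at full precision and rounded to
the nearest integer, the granularity at which such results are usually
quoted. On the motivating study's printed measurements these reproduce
79 % and 64 % reductions, a 45× supernatant ratio and doubling-time CVs
of 20/13/11 %; the analogous ratio for the tyrosine arm computes to 98.6
from the printed counts while the study text quotes 97×, presumably
derived from unrounded laboratory values — the package reports what the
arithmetic yields.

## The synthetic-data generator

`simulate_counts()` draws
`K_gs ~ NB(mean = f_s · mu_g · 2^(loading_g z_{s,c}) · 2^(lfc), dispersion = alpha)`
with log-uniform baseline means (default 5–5000, spanning the dynamic
range of miRNA counts), log-normal library-size factors with configurable
CV (default 0.2, typical library-to-library depth variation), one
standard-normal latent factor per planted cluster per sample, and planted
log2 fold changes per condition. Defaults mirror the motivating design:
three conditions (control and two exposures), three replicates each. The
`variance = mu + alpha mu²` parameterization matches the DE model, and
the single-factor log-linear cluster model gives monotone control of
within-cluster dependence. In the Poisson limit (`alpha ≤ 1e-8`) counts
are drawn from `rpois`.

What the generator does *not* emulate: sequencing reads and alignment
artifacts, zero-inflation beyond the NB, condition-specific dispersion
(a single global `alpha` is assumed, as nothing in the motivating study
constrains more), correlated library-size and condition effects, and
annotation errors in the target table. Passing tests therefore certify
the statistical machinery on NB-with-latent-factor data, not performance
on any particular real dataset.

`simulate_qpcr()` constructs Ct tables whose noiseless rER equals the
planted ratios exactly (the reference assay keeps constant Ct; the
target's treated Ct shifts by `−log ratio / log E`). `simulate_growth()`
follows `n0 · 2^(t/Td)` with optional log-normal noise.

## Problem sizes and runtime choices

The shipped tests use 2000 genes for null calibration and size-factor
recovery, 100 seeds × 50 miRNAs for cluster-recovery rates, 20 random
10-node matrices for threshold-selector verification, and 300-gene
datasets for DE power — sizes chosen so the full suite completes in about
a minute on one core while keeping Monte-Carlo standard errors around a
percentage point. `scripts/acceptance.R` recomputes the same quantities
from scratch at those sizes.

## Known limitations

* No dispersion shrinkage, GLM covariates, Cook's-distance outlier
  handling or independent filtering in the DE stage.
* Connected components are the only community structure; no weighted or
  modularity-based clustering.
* The MI estimator's small-sample bias limits network resolution (see
  above); the bin count and estimator are configurable but cannot
  overcome nine-sample quantization.
* The enrichment universe is the user's responsibility; the hypergeometric
  test is only as meaningful as that choice.
* Calibration-curve detection limits use the `3.3 σ / slope` convention
  and require at least three points.
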