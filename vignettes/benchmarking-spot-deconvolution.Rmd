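---
title: "Simulating and scoring spot deconvolution for spatial multiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring spot deconvolution for spatial multiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotbench)
```

## The problem

Spot-based spatial assays capture a small neighbourhood of tissue per
spot, so each spot's RNA or chromatin-accessibility profile is a sum over
an unknown mixture of cell types. Deconvolution methods estimate the
spots × cell-types proportion matrix using a dissociated single-cell
reference. Benchmarking those methods needs spatial datasets whose
composition is known exactly; `spotbench` constructs two complementary
kinds and provides the metric stack to score any method against them.

* **Silver standard** — spots assembled *in silico* by sampling cells
  from a dissociated reference and summing their profiles. Composition is
  known by construction; the noise model is whatever the reference
  carries, which favours no particular deconvolution model.
* **Gold standard** — pseudo-spots formed by spatially binning real (or
  synthetic) spatially tagged single cells and summing them. All spatial
  autocorrelation, segmentation noise, and cell-type zonation of the
  original tissue are preserved.

## The silver-standard model

For each spot the simulator draws two quantities from a Poisson-Gamma
mixture, i.e. a negative binomial parameterized by mean $\mu$ and shape
$\theta$ with variance $\mu + \mu^2/\theta$:

* $k$, the number of distinct cell types in the spot (tissue
  heterogeneity), upper-clamped to the number of types in the reference;
* $n$, the number of cells in the spot (spot density).

Both draws are lower-clamped at 1. The shape is shared and defaults to
$\theta = 20$, a mild overdispersion appropriate for capture-spot cell
counts; the means are the user-facing dials. The stock designs exposed by
`silver_presets()` use 1000 spots with ($\mu_k$, $\mu_n$) of (3, 5)
(sparse, homogeneous), (10, 15) (dense, heterogeneous), and two
four-region zonated mixtures of those regimes.

$k$ types are then chosen uniformly without replacement, the $n$ cells
are allocated to the chosen types by uniform multinomial with each type
guaranteed at least one cell, cells are sampled uniformly within each
type (with replacement only if a type's pool is exhausted), and counts
are summed per modality — exactly, in integer arithmetic, so per-spot
conservation is a testable invariant. The ground truth of a spot is its
member-cell type frequency vector (cell-count fractions, not
transcript-weighted fractions; the latter would tie the truth to library
size, which is a property of the measurement rather than the tissue).

### Numerical and distributional choices

**Clamping, not rejection.** Zero draws are clamped to 1 rather than
rejection-resampled. The induced bias is small and closed-form:
$E[\max(1, X)] = \mu + P(X = 0)$ with
$P(X=0) = (\theta/(\theta+\mu))^\theta$ — about $+0.012$ at
$\mu = 5, \theta = 20$. The unit tests check the sampler against this
closed form (and its two-sided analogue by pmf summation) rather than
against the unclamped mean.

**Rank-coupling of $k$ and $n$.** A spot declared to contain $k$
distinct types must contain at least $k$ cells. With independent draws
this fails with appreciable probability (about one spot in five under
the sparse design), and every post-hoc repair biases one of the two
means: reducing $k$ to $n$ deflates mean heterogeneity by roughly 15%,
while raising $n$ to $k$ inflates mean density by roughly 9%. The
simulator instead inverts both negative binomial CDFs on the *same*
uniform quantile per spot. Because the negative binomial family is
stochastically increasing in its mean at fixed shape, the cell-count
quantile dominates the type-count quantile whenever $\mu_n \ge \mu_k$,
so the constraint holds almost surely while *both marginals stay exactly
the clamped negative binomials* — the closed-form oracles above remain
valid for both. A final $n \leftarrow \max(n, k)$ guards configurations
with $\mu_k > \mu_n$. The price is a positive dependence between density
and heterogeneity within a spot, which we consider biologically
reasonable (crowded regions host more types) and document rather than
hide.

**Per-spot RNG substreams.** Spot $s$ uses the $s$-th element of a
prefix-stable seed stream derived from the master seed, so enlarging a
simulation from 100 to 1000 spots reproduces the first 100 spots
verbatim. Type choice and cell choice consume the spot's stream
sequentially; $k$ and $n$ share one quantile by design (above).

**Zonation geometry.** "Stripes" are $R$ equal-width vertical bands of
the unit square labelled by the spot's x-coordinate; "circles" are $R-1$
discs of radius $1/(2R)$ centred on the diagonal at $(i/R, i/R)$,
labelled by containment with ties to the lowest index, over a background
region 0. Per-region mean vectors map to zone labels in order. The
geometry is deliberately simple and fixed: zonation exists to give
regions *different compositions*, not to model tissue shape.

**Spot grid.** Spots sit on a near-square grid ($\lceil\sqrt{N}\rceil$
columns, last row possibly partial) covering the unit square. All
coordinates are dimensionless; no spot diameter or diffusion is modelled.

## The gold-standard aggregator

`grid_assign()` partitions the plane into half-open squares of side $s$
(a cell exactly on a boundary belongs to the right/upper square) and
`aggregate_pseudo_spots()` sums each occupied square with at least
`min_cells` cells (default 1), using the square centroid as the spot
coordinate. Shrinking $s$ towards 0 drives every pseudo-spot to
single-cell purity, which the tests exploit as a degenerate-limit check.
Square size and the minimum-cell filter are exposed because real
spatially tagged datasets differ widely in cell density.

## The synthetic multiome reference

The generator emulates the *structure* that deconvolution relies on, not
the full biology: each of $T$ cell types owns a disjoint block of marker
genes and marker peaks whose mean is `marker_fold_change` (default 8)
times the baseline. RNA counts are negative binomial (shape
`rna_overdispersion`, default 2 — typical gene-level overdispersion) with
a mean-centred log-normal per-cell size factor (`library_size_sigma`,
default 0.3, matching commonly seen depth spread); ATAC counts are
Poisson by default, reflecting that peak-level fragment counts are
usually well described without extra overdispersion (a negative binomial
option exists). Baseline means default to 0.5 (RNA) and 0.2 (ATAC),
giving the sparsity regimes typical of each modality.

What it does **not** emulate: fragment-level ATAC structure (Tn5
insertion, fragment lengths), doublets, batch effects, ambient
contamination, correlated marker programs, or continuous cell states.
Tests passing on this generator therefore demonstrate correctness of the
pipeline's bookkeeping and estimators under a known model — not
performance on real tissue, which is exactly why the package also accepts
real references through its MTX + TSV reader.

`expand_reference_series()` supports reference-size sensitivity studies:
starting from a base reference it adds cells sampled without replacement
from a larger pool, producing nested references at 2×, 4×, 8×, 16× the
base size.

## Feature selection

* *Highly accessible peaks*: rank by total fragment count (option:
  prevalence, the fraction of nonzero cells). Robust, signal-rich, but
  not type-discriminating.
* *Highly variable peaks*: cells are depth-normalized to the median
  depth, `log1p`-transformed, averaged within cell-type clusters
  (labels are taken as the predefined clusters), and peaks are ranked by
  the variance of those per-type means. The normalization and statistic
  are fixed and documented here since published pipelines differ in
  detail.
* *Highly variable genes*: cells depth-normalized to the mean total, the
  per-gene dispersion (variance/mean of normalized counts) z-scored
  within 20 equal-width bins of `log1p` gene mean, genes ranked by the
  normalized dispersion — the classic dispersion-based recipe.

All rankings break score ties by ascending feature index, with scores
compared at $10^{-9}$ resolution; z-scores in two-member bins are
structurally tied at $\pm 1/\sqrt 2$, and without the rounding rule their
order would be decided by floating-point noise instead of reproducibly.
Selections computed on the reference are imposed verbatim on the spatial
dataset (`apply_selection()`), which errors on missing features rather
than silently intersecting.

## Metrics

RMSE is computed per spot (root of the mean squared per-type error) and
averaged over spots; a globally pooled variant is exposed as an option
since conventions differ. JSD uses base-2 logarithms so each per-spot
value lies in $[0, 1]$, with defensive row renormalization and
$0 \log 0 = 0$. NMI normalizes mutual information by the arithmetic mean
of the two label entropies (max-normalization optional); identical
labelings score 1, and a zero-entropy labeling that is not identical to
its partner scores 0. Rare-type F1 thresholds presence at a proportion of
0.05 by default — about one cell in a typical 5–15-cell spot — and is
configurable. Majority ties are broken by the lexicographically smallest
type label. The paired strategy comparison uses an exact two-sided
Wilcoxon signed-rank test: for up to 25 nonzero paired differences the
null distribution of the statistic is built by dynamic programming over
sign flips of the (possibly tied, averaged) ranks, so constant-shift
pairs attain the exact floor $2/2^n$ instead of a tie-corrected normal
approximation.

## Baselines

The majority baseline predicts one type per spot with probability 1. Two
readings are shipped because the definition is ambiguous: the per-spot
*oracle* majority (default — an informed baseline that bounds what
majority-only prediction can achieve, and attains NMI 1 by construction)
and the *global* reference majority. The NNLS deconvolver builds each
type's signature as the mean of unit-total reference profiles, solves
Lawson–Hanson non-negative least squares per unit-total spot profile and
renormalizes; on noiseless convex mixtures of the signatures it recovers
weights to numerical precision, which the tests assert at $10^{-6}$.
It is a reference implementation for pipeline validation, not a
competitive method; external methods plug in through the spots × types
proportions TSV contract.

## Problem sizes and determinism

The shipped test-and-reproduction workloads use a 12-type, 1200–1800-cell
synthetic reference with 1000-spot simulations for composition
statistics, a 150-cell reference with 30,000 peaks / 20,000 genes for the
selection-size checks, and $10^5$-draw sampler checks — sizes chosen so
the full suite completes in a few minutes on one CPU while keeping
Monte-Carlo standard errors far below the effect sizes being asserted
(3-standard-error acceptance bands throughout). Every stochastic stage
takes an explicit seed; sub-seeds derive prefix-stably from it, and
rerunning any pipeline with the same configuration and seed is
byte-identical down to the written reports.

## Known limitations

Composition truth is cell-count-based; methods that estimate
transcript-mass fractions will show a systematic offset on spots with
depth-heterogeneous types. The silver standard inherits whatever
dissociation biases the reference carries. Zonation geometries are
axis-aligned archetypes, not tissue morphology. The gold-standard path
is only as good as the spatial tagging of its input. And the synthetic
reference's independence assumptions (block markers, independent genes)
make deconvolution *easier* than real tissue — treat absolute metric
values on synthetic data as upper bounds on real-data performance.
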