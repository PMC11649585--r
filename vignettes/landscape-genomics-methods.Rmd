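---
title: "Methods: from filtered SNPs to seed transfer zones"
author: "genoscaper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from filtered SNPs to seed transfer zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoscaper)
```

## What this package does

`genoscaper` is a landscape-genomics pipeline for reduced-representation
SNP data from patchily distributed plants, built around a desert-annual
use case: given genotypes at a few hundred to a few thousand SNPs from
dozens of sampling locations, environmental predictors, and a
habitat-probability surface from a species distribution model (SDM), it

1. filters genotypes and summarizes diversity and differentiation
   (Weir–Cockerham $\theta$, AMOVA $\Phi_{ST}$),
2. infers neutral population structure (PCA + k-means/BIC, discriminant
   assignment),
3. arbitrates isolation by distance (IBD), by habitat resistance (IBR)
   and by environment (IBE) with Mantel and partial-Mantel tests over
   geographic, environmental, least-cost and commute distances,
4. scans for environmentally associated loci with a redundancy-analysis
   (RDA) ordination,
5. models turnover of candidate allele frequencies with generalized
   dissimilarity models (GDM) and a gradient-forest-style tree ensemble,
6. delineates seed transfer zones by clustering GDM-predicted
   dissimilarities and extrapolating them with a weighted least-cost
   nearest-neighbor rule, and
7. projects genomic offset and zone boundaries under changed climate.

Every stage is exercised end-to-end on synthetic landscapes with known
truth; this vignette records the models, the tunable parameters, and the
design decisions a user should know about.

## The synthetic landscape generator

The generator ([`sim_config()`], [`simulate_landscape()`]) is first-class,
tested code, not a fixture: all validation rests on it.

**Environment.** Each of `n_env_layers` layers is Gaussian-smoothed white
noise (smoothing range `autocorr_range`, in cells) optionally mixed with a
linear trend in a random direction (`trend_weight`, default 0.3), then
standardized to zero mean and unit variance. A `range` of 0 gives pure
white noise; larger ranges give longer spatial autocorrelation, which the
tests verify with a lag-1 rook-neighbor correlation.

**Habitat.** A cellwise logistic model of the layers
(`plogis(intercept + sum(coef * layer))`) stands in for a fitted SDM;
values are probabilities in (0, 1). Cells with habitat 0 (or nodata) are
impassable in the resistance graph.

**Populations and frequencies.** Sampling locations are placed on cells
with habitat $\ge 0.2$ with a minimum spacing. Neutral locus $\ell$ draws
$\mathrm{logit}(p_{k\ell})$ jointly over locations $k$ from a Gaussian
with mean $\mathrm{logit}(p_{0\ell})$ and covariance
$\sigma^2 \exp(-D_{kj}/\varphi)$, where $D$ is by default the least-cost
habitat-resistance distance — the landscape is isolation-by-resistance by
construction; geographic- and environment-driven variants are config
switches for contrast scenarios. Adaptive loci instead follow
$\mathrm{logit}(p_{k\ell}) = \alpha_\ell + \beta_\ell\,
\mathrm{env}_k(m_\ell) + \varepsilon$, a logistic cline of slope $\beta$
on a standardized layer. This logit-normal model is *not* genealogical
(no coalescent, mutation or recombination); it was chosen because it is
cheap and gives closed-form control of $F_{ST}$-like structure, which is
exactly what the downstream estimators consume. Consequences: linkage
disequilibrium between loci is absent (apart from shared population
structure), site-frequency spectra are not realistic, and within-location
mating is panmictic. Passing tests therefore validate the estimators and
the pipeline logic, not demographic realism.

**Default conditions.** 40 × 40 cells of 1 km, 4 layers, 60 locations of
12 diploids, 780 neutral + 40 adaptive SNPs (≈ 5% adaptive), $\beta = 2$
per adaptive locus, $\sigma^2 = 1.2$, $\varphi$ set to half the median
pairwise resistance distance of the realized landscape (so the decay is
meaningful at the landscape's own scale). These mirror a Mojave Desert
RAD-seq sampling design (≈ 60 locations × 12–15 plants, several hundred
unlinked SNPs, a small minority of environment-associated loci). Genotypes
are Binomial(2, p); identical config + seed gives bit-identical output,
and fixtures round-trip through the VCF reader exactly.

## Genotype filters and genetic summaries

`apply_quality_filters()` applies, in a fixed documented order:
individuals with more than 30% missing data; SNPs with minor-allele count
below 3; SNPs whose mean depth exceeds the 99th percentile of the retained
set (per-SNP mean depth across called genotypes — per-genotype masking was
rejected for simplicity); SNPs with observed heterozygosity above 0.7. An
optional per-location call-rate screen (the assembly-level r-filter)
defaults to off because deposited datasets have usually passed it
upstream. The order matters and is tested; it is not assumed
interchangeable. `thin_one_snp_per_locus()` keeps one random SNP per
RAD-locus ID under a seed, since most downstream models assume unlinked
markers.

Pairwise $F_{ST}$ is the Weir–Cockerham (1984) variance-component
estimator; multi-locus values are ratios of summed components
$\sum a / \sum (a+b+c)$ (ratio-of-sums, the standard practice), negative
pair values are retained, and the overall summary is reported both as the
mean of pairwise values and as the all-location ratio-of-sums — data
summaries in the literature are usually the former. AMOVA is the
one-level squared-Euclidean-dosage partition with pairwise deletion of
missing values (each pair's squared distance is rescaled to the full SNP
count); $\Phi_{ST} = \sigma^2_{among}/\sigma^2_{total}$ with negative
components floored at zero. Both estimators are tested against literal
brute-force transcriptions of their formulas.

## Population structure

PCA runs on per-SNP mean-imputed, centered dosages. `select_k_bic()`
follows the k-means/BIC convention
$\mathrm{BIC}(K) = n\log(\mathrm{WSS}/n) + K\log n$. A practical caveat
the tests encode: this criterion behaves sensibly when *many* PCs are
retained (the usual find-clusters practice, where high-order PCs form a
noise floor); with only a handful of structure-bearing PCs it over-splits.
`dapc_assign()` fits linear discriminants on retained PCs, choosing the
PC count by cross-validation that withholds whole sampling locations (20%
at a time) — not random individuals, so assignment success is measured on
locations the model has never seen. Membership probabilities are the LDA
posteriors; the underlying posterior model of the classical DAPC
implementation is not published in detail, so this is a documented
stand-in with the same discriminant geometry.

## Resistance and distance matrices

`build_transition()` uses the habitat probability directly as conductance
(identity transform — the SDM→conductance transform is otherwise
arbitrary and this choice is logged), an 8-neighborhood with $\sqrt2$
diagonal correction, and edge conductance equal to the arithmetic mean of
the two cell conductances (the default transition rule of the standard
raster-resistance package; a geometric-mean rule is exposed). Edge cost is
inter-center distance divided by edge conductance; zero-habitat and nodata
cells have no edges. Least-cost distances are exact Dijkstra shortest
paths; commute distances come from sparse graph-Laplacian solves
(commute = effective resistance × graph volume, the circuit-theoretic
distance up to that constant factor) and are intended for desk-scale
grids (≤ ~10⁴ cells). Raster value extraction is containing-cell lookup,
never interpolation.

## Causal modeling

`mantel()` and `partial_mantel()` vectorize strictly-upper triangles,
permute rows and columns of one matrix jointly, and use the one-tailed
upper convention $p = (1 + \#\{r^* \ge r\})/(B+1)$ with $B = 999$ by
default (the source analyses do not state their count). The partial
statistic is the correlation of residuals of each matrix on the
conditioning matrix — algebraically the closed-form three-matrix partial
correlation, which a test verifies to $10^{-10}$. `causal_table()` runs
the nine-test battery on neutral and adaptive genetic distances and
applies an explicit verdict rule: IBR when
$r(\mathrm{gen} \times \mathrm{resist} \mid \mathrm{geo}) \ge 0.1$ while
$r(\mathrm{gen} \times \mathrm{geo} \mid \mathrm{resist}) \le 0$, IBD for
the reverse; both thresholds are config because the underlying logic is
qualitative ("remains positive", "collapses"). Following standard advice
for resistance comparisons, interpretation leans on $r$ magnitudes rather
than permutation p-values. On strongly spatially-confounded landscapes
the conditioned partial often lands slightly above zero, in which case
the battery honestly reports no clean verdict even though the resistance
partial dominates — the full table is always emitted.

## RDA genome scan

Predictors pass an iterative VIF < 10 screen. The ordination regresses
individual mean-imputed dosages (population-frequency response is an
option) on standardized predictors and eigen-decomposes the fitted
values; the variance decomposition identity (constrained + residual =
total) is tested to numerical precision and cross-checked against an
independent constrained-ordination implementation. Axis significance is a
sequential permutation test (response rows permuted, model refit, each
eigenvalue compared with its null distribution) at $\alpha = 0.05$.
Outliers are loci whose loadings lie more than 3 SD from the mean on a
significant axis; loadings are z-scored per axis before thresholding (the
raw-vs-standardized choice is ambiguous in common practice; z-scoring is
scale invariant). Each outlier is annotated with the environmental
variable most correlated with its dosages. A caveat the concordance
experiments exposed: when a large fraction of loci share one strong cline
they inflate the loading SD and mask each other at the 3-SD rule; with
clines spread over several predictors (the realistic case) recovery is
high. `merge_candidates()` unions the scan with externally supplied
candidate lists (e.g. a Bayesian $F$-model outlier method, which this
package deliberately does not re-implement) with per-method provenance.

Under the generator's default conditions the scan recovers ≥ 80% of
planted $\beta = 2$ clines at under 1% neutral false positives (20-seed
average), and its type-I error is nominal under the $\beta = 0$ null;
both are acceptance-tested.

## Generalized dissimilarity modeling

The response is Bray–Curtis dissimilarity of candidate-locus
allele-frequency vectors between location pairs (the common choice for
frequency tables; a precomputed matrix such as scaled $F_{ST}$ can be
substituted). Each predictor gets 3 monotone I-spline basis functions
(order 2, knots at min/median/max of observed values — the convention of
the reference GDM implementation; both counts are configurable).
I-splines are exact running integrals of the M-spline recursion
(piecewise Gauss–Legendre, tested against naive dense quadrature).
Matrix predictors (geographic distance, habitat resistance) enter their
splines on the raw pairwise distance.

The model is $d = 1 - e^{-\eta}$ with
$\eta = \alpha + \sum_{jk} \beta_{jk}\lvert I_{jk}(x_{1j}) -
I_{jk}(x_{2j})\rvert$, all coefficients non-negative, fit by IRLS with an
inner non-negative least-squares solve and binomial-type deviance;
convergence is a relative deviance change below $10^{-6}$ (measured
against the null deviance so that near-perfect fits also terminate), with
a 100-iteration cap. The spline height $\sum_k \beta_{jk}$ is the total
turnover attributed to predictor $j$; predictors whose coefficients are
all zero are reported "not selected". Noise-free self-consistency
recovery (heights within 10%, inactive predictor at zero) is
acceptance-tested, as are nesting monotonicity of deviance explained and
invariance to affine predictor rescaling.

**Genomic offset** is
$1 - \exp(-\sum_j \lvert f_j(x^{fut}) - f_j(x^{cur})\rvert)$ per cell,
with $f_j$ the fitted spline transform. The intercept is excluded so an
unchanged climate gives exactly zero offset; whether reference
implementations include it is not documented, and the zero identity was
judged more important than mimicry.

## Turnover forest

For each candidate SNP an ensemble of regression trees (rpart, bootstrap
resamples) is grown on the environmental predictors. Predictor randomness
is per tree (random subspace, `mtry = ceiling(p/3)` predictors per tree)
rather than per split — rpart does not expose per-split candidate
sampling, and the subspace variant preserves the decorrelation the
ensemble needs. SNPs with positive out-of-bag $R^2$ are retained.
Permutation importance is the OOB error increase when a predictor is
permuted, computed per tree; when predictors correlate above the 0.7
threshold, permutation is within quartile strata of the most correlated
companion (a compact form of the conditional-importance convention).
Per-predictor importance is the SNP-averaged product of the SNP's $R^2$
and its normalized importance, averaged over **all** fitted SNPs with
non-retained SNPs contributing zero — conditioning the average on
retained SNPs would bias pure-noise panels to visibly positive
importance, and the null calibration (importance ≈ 0, few SNPs retained)
drove this choice. Cumulative turnover functions bin split improvements
at their thresholds, density-standardize by the data density along the
gradient, cumulate, and rescale so the plateau equals the predictor's
importance; planted step-clines concentrate ≥ 50% of the rise within
±0.5 SD of the true threshold in simulation. Tree count defaults to 2000
(the conventional setting); tests and the acceptance script use a few
hundred, which the importance rankings are insensitive to.

## Seed transfer zones

Locations are clustered on GDM-*predicted* dissimilarities with Ward
linkage (the squared-increase "ward.D2" update; the variant is otherwise
unspecified in common practice). Candidate cuts $k$ are scored by mean
silhouette width computed directly on the dissimilarity matrix (no
embedding) and by perMANOVA $R^2$ from the standard squared-distance
partition; $k$ is the silhouette argmax with an explicit override, since
management often wants a finer split (e.g. both 4- and 6-zone versions)
regardless of the statistical optimum.

Cell assignment combines, for every location $p$, the accumulated
least-cost surface over habitat conductance and the Euclidean distance in
GDM-transformed predictor space from $p$'s cell, as
$0.6\,\mathrm{ACD}' + 0.4\,\mathrm{ED}'$. The two components have
incommensurate units; **both are min–max normalized to [0, 1] over all
(location, cell) values before weighting** — this is the largest single
design decision in the module, is prominently configurable, and any
alternative normalization changes zone boundaries. Each cell joins the
cluster of its minimum-cost location (ties to the lowest location index,
logged); cells below the habitat clip (0.2 — marginal habitat is included
deliberately) or unreachable from every location become nodata. Future
projection re-runs the identical algorithm on a future-projected habitat
surface and future-transformed predictors and emits a
same/changed/lost/gained change raster whose counts partition the current
suitable area; idempotence on unchanged inputs and clip monotonicity are
acceptance-tested. Zone-vs-ancestry agreement is an adjusted Rand index.

## Numerical and engineering choices

* Rasters are a lightweight in-memory grid class with plain-text ESRI
  ASCII grid I/O; coordinates are projected, cell-center based, row-major
  from the top-left, 0-based only internally. No CRS handling beyond a
  tag: all inputs must share one projected CRS.
* All randomness flows from explicit integer seeds; child seeds are
  derived deterministically and stay below $2^{31}$.
* Near-singular neutral covariances are repaired by escalating diagonal
  jitter (logged); degenerate Mantel inputs (constant matrices, collinear
  conditioning) raise errors or flagged degenerate results rather than
  silent numbers.
* Problem sizes in the test-suite and acceptance script: oracles run on
  toys (2 populations, 3×3 grids, 4! permutations); calibration uses 200
  null replicates; recovery uses the generator's default conditions over
  20 seeds; the concordance experiment compares an 800-SNP and a
  2700-SNP dataset from one truth at 32 locations × 10 plants. These are
  the sizes at which the checked properties stabilize while the whole
  suite stays comfortably interactive.

## Known limitations

* The frequency model is non-genealogical: no LD, no drift trajectories,
  no realistic site-frequency spectrum. Conclusions about estimator
  behavior under strong linkage or complex demography need a coalescent
  or forward simulator upstream.
* The RDA scan is unconditioned (no latent-factor correction for
  structure), matching the source design; on landscapes where neutral
  structure aligns tightly with the environment its false-positive rate
  rises with $\sigma^2$.
* Mantel-type tests have well-known inflation under spatial
  autocorrelation; the battery mitigates by comparing $r$ magnitudes
  across competing hypotheses rather than trusting p-values.
* Commute distances require the dense-ish Laplacian solve and are not
  meant for ecoregion-scale rasters; least-cost distances scale much
  further.
* Zone boundaries inherit every upstream choice (candidate set, GDM
  response, normalization rule, weights); the package makes each explicit
  rather than pretending the composition is canonical.
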