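---
title: "Methods: registration, composite maps and criticality statistics for the zebrafish tailbud"
author: "tailbud package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registration, composite maps and criticality statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailbud)
```

# The problem

Zebrafish neuromesodermal progenitors (NMps) are bipotent axial progenitors
that co-express *sox2* and *tbxta* and feed both the spinal cord and the
paraxial mesoderm during late somitogenesis (roughly the 18-30 somite
stages). The transition-state picture of differentiation predicts a
transient window of elevated gene-expression stochasticity just before
commitment. Testing that prediction on fixed imaging data requires three
computational ingredients, all provided by this package:

1. **Registration and imputation.** Each imaged tailbud is reduced to a
   point cloud of segmented nucleus centroids carrying per-nucleus HCR
   intensities. Stage-matched samples are aligned rigidly and their gene
   channels imputed onto one target cloud, producing a multi-gene
   *composite map* that no single stain could provide.
2. **Per-cell indices.** On the composite map, double-positive cells inside
   the anatomically defined NMp region are called as in-silico NMps and
   scored with the correlation-weighted NM index; comparing the index, the
   fate-mapped domain and Wnt activity classifies cells as Congruent,
   Compliant or Rebellious.
3. **Population statistics.** Heterogeneity is quantified by the critical
   transition index and pairwise-distance transcriptional noise on
   single-cell count matrices, and by a family of discrete Shannon entropy
   estimators on the NM index distribution.

# Rigid registration

Tailbuds of the same stage are morphologically consistent and the field of
view is standardized by cropping to the nuclei posterior to the notochord
tip (`cropPosterior()`), so a rigid motion (rotation plus translation, no
shearing or stretching) is an adequate transform class; `RigidTransform`
validity enforces an orthonormal, determinant +1 rotation block on every
transform the pipeline returns.

Alignment is a two-stage pipeline (`registerClouds()`):

* **Coarse stage** (`ransacCoarse()`): both clouds are voxel-downsampled at
  the mean nearest-neighbour spacing, per-point normals are estimated from
  k = 30 neighbourhoods (oriented toward the cloud centroid), and an
  FPFH-style 33-bin local descriptor is computed with radius five times the
  voxel size. Candidate correspondences are nearest neighbours in
  descriptor space; each RANSAC iteration samples three candidates, prunes
  them by edge-length similarity, fits a least-squares rigid transform and
  scores inliers at the correspondence threshold. If no pruned triplet
  yields at least three inliers a rescue pass without the prune is run; a
  coarse alignment that still finds no inlier set raises an error. The
  stage is stochastic but fully seeded.
* **Fine stage**: point-to-plane ICP (`refineICP()`), chosen over
  point-to-point for its faster convergence on smooth surfaces, iterates
  nearest-neighbour matching and a linearized Gauss-Newton update until the
  relative residual change falls below `tol` (default 1e-8) or `maxIter`
  (50). When the clouds share a normalized channel (the composite maps use
  *sox2*), colored ICP (`refineColoredICP()`) adds a photometric residual
  comparing the source intensity with a first-order expansion of the target
  color field on the tangent plane; the joint objective weights geometry
  0.968 and color 0.032 by default, following the published colored
  point-cloud registration formulation, and `colorWeight = 0` reduces
  exactly to plain ICP.

**Correspondence threshold.** `maxCorrDist` defaults to twice the mean
nearest-neighbour spacing of the target, a scale at which a correct
alignment matches essentially every point while misalignments are penalized.

**Quality metrics.** Fitness is the matched source fraction; inlier RMSE
and inlier MAE are computed over matched pairs only and therefore flatter
registrations whose unmatched fraction grows. The scaled metrics divide by
fitness (`registrationMetrics()`): division (rather than multiplication)
inflates the error as the matched fraction drops, which is the direction
the bias correction must act; with fitness 0 the scaled metrics are
reported as `Inf`.

**Validation procedures.** `permutationTestMAE()` builds the null MAE
distribution by permuting the target color array 10,000 times (Gaussian
method-of-moments fit, one-sided lower-tail p), asking whether the reported
correspondence mapping carries more color information than a random one.
`noiseCalibration()` registers noise-shifted copies of a cloud back onto
the original over a grid of positional noise SDs (default 0-30 in
coordinate units, five replicates per level) and records fitness plus
scaled metrics; failed registrations at a grid point are flagged in a
`failed` column, never silently dropped.

# Imputation and composite maps

`imputeChannel()` implements the three-outcome policy along the
correspondence map. A uniquely matched target copies its source value; a
multiply matched target aggregates by the median (default; the mean is
available); an unmapped target is resolved by `"null"` (set to 0),
`"complete"` (keep the target's own channel) or the default `"knn"`, the
mean of the k = 5 nearest target points among those already assigned under
the first two outcomes. Restricting the k-NN pool to outcome-(i)/(ii)
points breaks the circularity of imputing from imputed values; distance
ties break toward the lower point index so the result is deterministic.
All three aggregation modes are convex combinations, so imputed values can
never leave the range of the contributing source values.

`buildComposite()` registers each source onto the target with colored ICP
on the common channel (default `sox2`), rejects sources whose fitness falls
below 0.5 (configurable; a permissive default that catches only gross
misalignments), and imputes every source channel the target does not
already carry. A channel offered by several sources is taken from the
first accepted source carrying it, and each imputed channel records its
contributing sample, registration metrics and per-point policy labels in
the provenance slot. Five sources contributing six new genes onto a
*sox2*+*tbxta* target yield the eight-channel map.

**NMp calling.** Each composite channel is background-suppressed by
`thresholdRescale()`: values strictly below the 0.7 quantile (linear
interpolation between order statistics, the common type-7 convention,
computed per gene over all points) are zeroed and the vector min-max
rescaled. "Positive" thereafter means strictly greater than zero.
`identifyNMps()` returns the double-positive cells inside the user-supplied
spatial region (boxes or a per-point label vector — the anatomical
delineation cannot be automated from text) and reports excluded
double-positives (hypochord-like and aberrant cells) separately.
`probabilityMap()` counts per-target-cell hits across sources, with a
display floor of 2 so that single-source coincidences are not shown.

# The NM index and congruence classes

For cell *j* the neural index is
$N_j = sox2_j + \sum_{k=1}^{G} \tilde\rho_k (1 - \epsilon_k)\,Gene_{kj}$,
where $\tilde\rho_k$ is the median Pearson correlation of gene *k* with
*sox2* across same-stage samples and $\epsilon_k$ the interquartile range
of those correlations; the mesodermal index $M_j$ is defined symmetrically
on *tbxta*, and $NM_j = N_j - M_j$ with positive values indicating neural
bias. The $(1-\epsilon_k)$ factor down-weights genes whose anchor
correlation is unstable across samples; when correlations spread so widely
that $\epsilon_k > 1$ the formula is applied literally and a warning is
raised. Samples in which a gene or anchor has zero variance contribute no
correlation and are dropped from the median/IQR rather than imputed. The
unweighted `naiveIndex()` (*sox2 - tbxta*) is the exact G = 0 reduction,
and `categoricalIndex()` implements the fixed grouping
$(sox2 + cdh6) - (tbxta + tcf)$.

`classifyCongruence()` compares NM state (neural above `nmBand`, mesodermal
below `-nmBand`; the band defaults to 0, a strict sign rule, because no
printed thresholds exist for the three-way split) with the fate-mapped
domain. Incongruent cells split by *tcf*: high tcf is treated as consistent
with a mesodermal state (canonical Wnt drives the mesodermal program), so
an incongruent cell whose tcf level contradicts its own NM state is
Rebellious, otherwise Compliant; the tcf threshold defaults to the median
across the scored cells. Indecisive cells stay unassigned, making the
four-way classification exhaustive and exclusive.

# Criticality statistics

`qcFilter()` removes cells whose log library size or log detected-gene
count lies more than 3 MADs (standard 1.4826 consistency constant,
two-sided) from the median, then removes genes with zero total count —
cells before genes, and the operation is idempotent.

`criticalIndex()` is the ratio of the mean absolute gene-gene Pearson
correlation (across cells) to the mean absolute cell-cell correlation
(across genes). Absolute values are used in both terms, following the
index's original formulation, although some descriptions omit them;
zero-variance rows/columns are dropped with a warning and fewer than two
survivors on either axis is an error. `bootstrapCriticalIndex()` equalizes
cluster sizes by resampling 200 cells with replacement per replicate,
10,000 replicates by default, computed on per-cluster marker genes and
fully seeded. Cluster contrasts are tested with the two-sample
Wilcoxon-Mann-Whitney test from `stats`.

`transcriptionalNoise()` measures all pairwise cell-cell Euclidean
distances on log-normalized expression of the top 2000 highly variable
genes (`selectHVGs()`: variance ranking of log1p median-library-normalized
counts). The simple library-size/log1p normalization is a deliberate,
documented choice: it keeps the statistic self-contained, monotone in the
biological dispersion, and free of model-fitting steps that belong to
upstream single-cell workflows.

# Entropy estimation

The NM index is continuous, so entropies are computed on histogram counts.
No binning rule accompanies the published entropy values, so the default
here is Freedman-Diaconis edges computed on the pooled multi-stage data and
reused for every stage — pooling makes stages comparable, and explicit
edges can always be supplied. Counts follow the right-closed convention
with the lowest edge included. Five estimators are provided (all in nats):
maximum-likelihood plug-in, Miller-Madow ($H_{ML} + (\hat m - 1)/(2n)$),
Dirichlet pseudocount smoothing with Jeffreys ($a = 1/2$) and Laplace
($a = 1$) priors, and a James-Stein-type shrinkage toward the uniform
distribution with the closed-form variance-over-misfit intensity clipped to
[0, 1] (fully shrunk at n = 1). `jackknifeSE()` supplies leave-one-out
standard errors with the binning held fixed across deletions; with the
sample mean as estimator it reproduces $s/\sqrt{n}$ exactly, which the
tests assert.

Because the imaging data behind the published composite maps are available
only on request and the binning is unstated, absolute reproduction of the
published stage entropies is not attempted; the package instead verifies
the estimator identities exactly and the stage-ranking behaviour on
synthetic series.

# Synthetic data: what it does and does not emulate

`simulateTailbud()` draws points uniformly in an ellipsoid (default
half-axes 60 x 40 x 40 um, ~900 points, the scale of a segmented tailbud)
with logistic anchor gradients along the anterior-posterior axis meeting in
a co-expression zone, plus optional channels with a requested gene-anchor
correlation (realized by an affine construction, so min-max normalization
preserves it exactly in expectation). `perturbCloud()` applies a rigid
motion, Gaussian positional noise, clamped intensity noise and exact-count
dropout. `simulateExpression()` draws negative-binomial counts with
cluster-specific dispersion and a shared-latent-factor module structure —
the minimal model in which gene-gene coordination and cell-cell dispersion
can be dialed independently, which is exactly what the criticality
statistics measure. `simulateTransitionSeries()` draws per-stage NM values
from a two-component mixture (neural-fated cells around +0.3,
mesoderm-fated around -0.3) with stage-specific dispersion and injects a
chosen fraction of rebellious cells (neural state, high tcf) into the
mesoderm-fated domain.

These generators reproduce the *structure* the statistics respond to, not
real tailbud data: they have no segmentation error, no anatomical
asymmetry, no spatial autocorrelation in expression noise, and their
mixture NM distributions are cleaner than imaged ones. Passing tests
therefore demonstrate correctness of the algorithms and recoverability of
planted effects, not biological accuracy on microscope data.

Every generator is a pure function of its seed; identical seeds give
bit-identical output.

# Problem sizes and numerical choices

The test and acceptance workloads use 150-300-point clouds, 500 RANSAC
iterations for the calibration sweeps (1000 by default), bootstrap sizes of
200 cells x 1000 replicates for cluster contrasts, 10,000 permutations for
the MAE test, 100-run repetitions for the stage-ranking study, and stage
sizes of 300-1000 cells — sizes at which every statistic is stable while
the full suite completes in minutes. Degenerate inputs fail loudly rather
than silently: empty crops, collinear normal neighbourhoods, constant color
arrays, all-equal vectors under `thresholdRescale()`, and sub-minimal
matrices for the critical index all raise informative errors, as the tests
exercise.

# Known limitations

* Registration is rigid by design; tissues with shrinkage or large shape
  variation would need a deformable stage that is out of scope here.
* k-NN imputation assumes local spatial autocorrelation of expression;
  during a transition state, averaging can understate heterogeneity.
* The NMp spatial region must be supplied by the user; anatomical
  delineation is not automated.
* The critical index is undefined for near-constant submatrices and is
  sensitive to marker-gene choice; the bootstrap equalizes cell numbers
  but not gene-set quality.
* Entropy values depend on the binning; only comparisons made under shared
  edges are meaningful.
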