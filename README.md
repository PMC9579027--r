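# tailbud

Registration, composite expression maps and criticality statistics for the
zebrafish tailbud.

## What this package is for

Zebrafish neuromesodermal progenitors (NMps) are bipotent axial progenitors
that co-express *sox2* and *tbxta* and differentiate into spinal cord and
paraxial mesoderm during late somitogenesis. Quantifying how noisy this
population is — and whether a transient surge of heterogeneity precedes
commitment — requires combining information across many fixed, stained
samples and across data modalities. `tailbud` provides the full toolchain
for imaging groups and computational biologists working on this system:

* **Rigid point-cloud registration** of segmented-nucleus centroid tables:
  seeded RANSAC coarse alignment over FPFH-style local descriptors,
  refined by point-to-plane ICP, or by colored ICP when the samples share
  a normalized channel (typically *sox2*). Quality is reported as fitness,
  inlier RMSE and inlier MAE, plus fitness-scaled versions
  (`scaled = inlier / fitness`) that stay honest as the matched fraction
  drops. Validation tools include a 10,000-iteration permutation test of
  the post-registration color MAE and a positional-noise calibration curve
  (SD 0–30).
* **Composite maps**: each source sample is registered onto a target cloud
  and its gene channels imputed under the three-outcome policy (unique
  targets copy; multi-mapped targets take the median; unmapped targets take
  the mean of their k = 5 nearest assigned neighbours), with full per-channel
  provenance. Channels are background-suppressed (0.7-quantile threshold,
  min-max rescale), double-positive cells inside the NMp region become the
  in-silico NMps, and repeated mappings build an NMp probability map
  (display floor 2).
* **The NM index**: per cell *j*,
  `NM_j = N_j − M_j` with
  `N_j = sox2_j + Σ_k ρ̃_k (1 − ε_k) Gene_kj`
  (and `M_j` symmetric on *tbxta*), where `ρ̃_k` and `ε_k` are the median
  and IQR of gene *k*'s Pearson correlation with the anchor across
  same-stage samples. Positive NM means neural bias. Cells are classified
  Congruent / Compliant / Rebellious by comparing NM state, fate-mapped
  domain and *tcf* (Wnt) level.
* **Criticality statistics** on single-cell counts: MAD-based QC, the
  critical transition index `I_c` (mean |gene–gene r| / mean |cell–cell r|)
  with a cluster-balanced bootstrap (200 cells × 10,000 draws), and
  pairwise-distance transcriptional noise over the top 2000 highly
  variable genes.
* **Entropy estimators** for the NM index distribution: maximum likelihood,
  Miller–Madow, Dirichlet (Jeffreys and Laplace priors) and James–Stein
  shrinkage, in nats, with leave-one-out jackknife standard errors.
* **Synthetic generators** for tailbud-shaped clouds, noise-shifted
  replicates, clustered negative-binomial count matrices and staged
  transition series — used throughout the tests to verify that planted
  effects are recovered.

## Worked example

Build a two-source composite map from synthetic tailbuds, call in-silico
NMps, and score them:

```r
library(tailbud)

genes <- list(cdh6 = list(anchor = "sox2", correlation = 0.6),
              tcf  = list(anchor = "tbxta", correlation = 0.5))
target  <- simulateTailbud(nPoints = 400, sampleId = "target",  seed = 1)
sourceA <- simulateTailbud(nPoints = 400, sampleId = "sourceA", seed = 1,
                           genes = genes["cdh6"])
sourceB <- simulateTailbud(nPoints = 400, sampleId = "sourceB", seed = 1,
                           genes = genes["tcf"])
sourceA <- perturbCloud(sourceA, posSd = 1, seed = 2)
sourceB <- perturbCloud(sourceB, posSd = 1, seed = 3)

map <- buildComposite(target, list(sourceA, sourceB),
                      commonChannel = "sox2", seed = 4)
map
#> CompositeMap: 400 points, 4 channel(s) [sox2, tbxta, cdh6, tcf], 2 imputed, 0 source(s) rejected
round(provenance(map)$cdh6$metrics, 4)
#>          fitness       inlierRMSE        inlierMAE scaledInlierRMSE  scaledInlierMAE
#>           1.0000           1.7333           0.0028           1.7333           0.0028
```

Fitness 1 with an RMSE near the injected positional noise says the sources
aligned; the tiny inlier MAE says the shared *sox2* channel agrees across
the matched pairs. Threshold, call NMps and compute the index:

```r
map <- thresholdCompositeMap(map, q = 0.7)
calls <- identifyNMps(map, region = abs(coords(compositeTarget(map))[, "x"]) < 30)
length(calls$nmps)
#> [1] 14

samples <- lapply(5:7, function(i) as.data.frame(channels(
  simulateTailbud(nPoints = 300, genes = genes, seed = i))))
stN <- anchorCorrelationStats(samples, c("cdh6", "tcf"), "sox2")
stM <- anchorCorrelationStats(samples, c("cdh6", "tcf"), "tbxta")
print(stN, digits = 2)
#>   gene rhoMedian   iqr weight
#> 1 cdh6      0.60 0.013   0.59
#> 2  tcf     -0.19 0.046  -0.18

cells <- as.data.frame(channels(compositeTarget(map)))[calls$nmps, ]
tab <- nmIndexTable(cells, stN, stM)
round(summary(tab$NM), 3)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  -0.485   0.017   0.154   0.189   0.355   0.629

ent <- entropyEstimates(tab$NM, se = TRUE)
round(ent$estimates, 3)
#>      ml      mm jeffrey laplace  shrink
#>   1.272   1.379   1.303   1.322   1.386
round(ent$se, 3)
#>      ml      mm jeffrey laplace  shrink
#>   0.171   0.206   0.097   0.068   0.024
```

Only 14 of 400 cells are double-positive inside the region after
thresholding — in-silico NMps are a minority population, as in real
tailbuds. The positive median NM reflects the cdh6-driven neural weighting
of this toy gene set, and the five entropy estimates agree to within their
jackknife errors.

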