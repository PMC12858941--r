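# traitmapper

Gridded community-trait mapping for macroecology: from species
observations, vegetation plot surveys and a species trait database to
continuous trait maps with uncertainty layers — validated by spatially
blocked cross-validation and testable end to end on a synthetic world with
known ground truth.

## Who this is for

Ecologists and spatial modellers who build community-weighted mean (CWM)
trait maps by combining:

* **vegetation surveys** (plot × species relative cover), which yield plot
  CWMs: `CWM = Σ cover_s · mean_s / Σ cover_s` over species matched in a
  trait database;
* **opportunistic occurrence records** (point observations without
  abundance), which after trait tagging and per-cell averaging yield
  frequency-weighted means (FWM), an occurrence-based approximation of the
  CWM;
* **gridded environmental predictors**, against which the gridded labels
  are modelled with missing-value-tolerant gradient-boosted regression
  trees.

Because real data streams of this kind are restricted-access and huge, the
package ships a first-class synthetic-world generator (autocorrelated
environments, Gaussian-niche communities, clustered surveys, biased
occurrences, incomplete trait measurements) so that the whole pipeline is
reproducible and verifiable at desk scale.

## What the method does

1. Match species names across tables (two-word binomial truncation,
   case-insensitive), compute species trait means, plot CWMs and tagged
   occurrences.
2. Grid labels at one or more equal-area resolutions; subsample occurrence
   cells to 10–500 records; build SCI (survey), CIT (occurrence) and COMB
   (merged, survey-precedence) label subsets; filter training rows to at
   least 60% predictor completeness; symmetrize labels with a
   maximum-likelihood Yeo–Johnson transform.
3. Estimate the spatial autocorrelation range of survey CWMs (Matheron
   semivariogram + spherical WLS fit), tessellate the domain into
   range-sized hexagons, and pick the best of 100 random fold assignments
   by mean pairwise Kolmogorov–Smirnov p-value.
4. Fit boosted-tree models per (trait, resolution, subset) with
   source-balancing weights and optional permutation-importance pruning;
   validate leave-one-fold-out, always against held-out *survey* CWMs.
5. Emit per-pixel coefficient of variation (sd/mean over the fold-model
   prediction stack), the dissimilarity index (DI) and the area of
   applicability (AOA, threshold `Q75 + 1.5·IQR` of the training DI), and
   pooled metrics (Pearson r, nRMSE, R²) with per-stratum breakdowns.
   Maps are written as quantized (int16) multi-band bundles in plain-text
   ASCII-grid format with a JSON sidecar.

## Worked example

```r
library(traitmapper)
res <- runPipeline(list(seed = 1,
  world = list(nCols = 40, nRows = 40, nPlots = 400, nOcc = 20000,
               nSpecies = 30),
  traits = "sla", resolutions = c(1, 4), folds = list(nSim = 50),
  model = list(nrounds = 120)))
print(res$metrics, digits = 3)
```

```
  trait resolution subset   n     r  nrmse    r2 rangeKm pctInsideAOA meanCOV
1   sla          1    SCI 334 0.993 0.0265 0.984      16         98.5  0.0122
2   sla          1    CIT 334 0.967 0.0572 0.925      16           NA      NA
3   sla          1   COMB 334 0.978 0.0436 0.956      16        100.0  0.0239
4   sla          4    SCI  92 0.951 0.0745 0.897      16         98.0  0.0232
5   sla          4    CIT  92 0.963 0.0659 0.919      16           NA      NA
6   sla          4   COMB  92 0.961 0.0667 0.917      16        100.0  0.0203
```

Reading the table: each row is one (trait, resolution, subset) model task.
`r` and `nrmse` score the pooled spatial-CV predictions against held-out
survey CWMs on the transformed label scale (`n` pairs); `rangeKm` is the
fitted semivariogram range that sized the hexagon folds; `pctInsideAOA` is
the share of predicted pixels whose predictor profile lies inside the area
of applicability, and `meanCOV` the average ensemble coefficient of
variation (both computed for the subsets that produce final maps). Here
the occurrence-only models (CIT) trail the survey-based ones at the finest
resolution, and merging sources (COMB) widens the AOA relative to SCI —
the qualitative pattern this modelling design is built around.

Passing `outDir =` writes surveys/occurrences/trait tables (CSV), match
reports and metrics (JSON/CSV) and quantized trait map bundles
(`*_prediction.asc`, `*_cov.asc`, `*_aoa.asc` + sidecar) with full
provenance.

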