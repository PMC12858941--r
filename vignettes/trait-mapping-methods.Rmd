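---
title: "Mapping community-weighted mean traits from surveys, occurrences and trait databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping community-weighted mean traits from surveys, occurrences and trait databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Continuous maps of community-level plant traits (specific leaf area, plant
height, wood density, ...) are built by relating *gridded trait labels* to
*gridded environmental predictors*. The labels come from two very different
kinds of biodiversity data:

* **Vegetation surveys** record every species in a plot together with its
  relative cover, so a plot yields a *community-weighted mean* (CWM): for a
  trait $t$ with species means $\bar{t}_s$ and relative covers $w_s$,

  $$\mathrm{CWM} = \frac{\sum_s w_s\,\bar{t}_s}{\sum_s w_s}.$$

* **Opportunistic occurrence records** (citizen-science style point
  observations) carry no abundance. Each record is tagged with its species'
  mean trait, and the per-grid-cell average of tagged records — the
  *frequency-weighted mean* (FWM) — approximates the CWM when records
  arrive roughly in proportion to cover.

Species means themselves come from a trait-measurement database that covers
only part of the species pool. Names are matched across the three tables by
truncating to the first two lowercase words (the primary binomial);
single-token names are treated as unmatched, never guessed.

`traitmapper` implements this label construction, the gridded modelling
that follows, and — because the real data streams are restricted-access and
enormous — a fully synthetic miniature world with known ground truth so
every stage can be exercised and verified at desk scale.

# Pipeline overview

1. **Label grids.** Plot CWMs and tagged occurrences are projected onto an
   equal-area grid (half-open cells, floor rule) at one or more
   resolutions. Occurrences are subsampled per cell to between `minOcc =
   10` and `maxOcc = 500` records; cells below the minimum are dropped,
   cells above it are reduced by uniform sampling without replacement.
   Three label subsets are built per resolution: survey-only (SCI),
   occurrence-only (CIT), and their merge (COMB) in which survey values
   take precedence wherever both sources occupy a cell.
2. **Training tables.** Labels are matched with the predictor stack by
   cell; rows with strictly fewer than 60% non-missing predictors are
   excluded. Labels are symmetrized with a Yeo–Johnson power transform
   whose $\lambda$ is fitted by maximum likelihood on the survey labels and
   reused unchanged for every subset, so all validation happens on one
   fixed transformed scale.
3. **Spatial blocking.** The spatial autocorrelation range of the survey
   CWMs is estimated at the finest resolution with a Matheron empirical
   semivariogram and a weighted-least-squares spherical model fit. The
   domain is tessellated into flat-top hexagons whose across-flats width
   equals the fitted range, and hexagons are assigned to $K = 5$ folds. One
   hundred random assignments are simulated; for each, two-sample
   Kolmogorov–Smirnov tests compare the label distributions of all fold
   pairs, and the assignment maximizing the mean p-value is kept.
4. **Models.** Each (trait, resolution, subset) task fits
   missing-value-tolerant gradient-boosted regression trees (xgboost
   backend; missing values are routed to the loss-minimizing side of each
   split). In COMB, occurrence rows are down-weighted by
   $n_\mathrm{survey}/n_\mathrm{occurrence}$ so both sources contribute
   equal total weight. Optional backward-elimination pruning drops features
   whose permutation importance on an internal held-out fold is
   non-positive. Validation is leave-one-fold-out and always scores against
   *survey* CWMs of the held-out fold — including for CIT models, which
   never see survey data in training.
5. **Uncertainty.** Each fold model predicts a full map; the per-pixel
   coefficient of variation (sd/mean over the $K$ maps, original trait
   units) summarizes ensemble spread. The dissimilarity index (DI) of each
   pixel is its nearest-neighbour distance to the training rows in
   z-standardized predictor space, divided by the mean cross-fold
   nearest-neighbour distance of the training rows; the area of
   applicability (AOA) is the region with DI at or below
   $Q_{75} + 1.5\,\mathrm{IQR}$ of the training DI distribution.
6. **Scoring.** Pooled observed-vs-predicted pairs over all folds give
   Pearson *r*, RMSE, nRMSE (normalized by the observed range) and
   $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$, overall and per stratum.

# The synthetic world

`simulateWorld()` generates, under one seed:

* **Environment layers**: stationary random fields produced by
  Gaussian-kernel smoothing of white noise. The kernel bandwidth is
  calibrated (factor 0.22 between the requested range and the kernel sd)
  so that the package's own spherical fit recovers approximately the
  requested autocorrelation range from the realized field.
* **A species pool** with unique binomials, Gaussian niches (uniform
  optima and breadths per environmental axis) and true trait values. The
  `optimumLinked` trait distribution ties a trait to the niche optimum on
  one axis, producing a smooth CWM surface as a function of the
  environment — the structure the models are supposed to learn.
* **Communities**: per-cell covers proportional to
  $\exp(-\sum_a (e_a - \mu_{sa})^2 / 2\sigma_{sa}^2)$, renormalized;
  species below an absence floor ($10^{-4}$) are absent.
* **Surveys**: a clustered point process (uniform cluster centres,
  Gaussian dispersion) recording each plot cell's complete community —
  plot CWMs are then exact functionals of the latent field, which is what
  makes the noise-free recovery tests exact. Top-$k$ truncation is
  available to emulate incomplete plots.
* **Occurrences**: locations drawn proportional to an effort surface times
  detectable cover; species drawn proportional to cover times
  per-species detectability. Spatial bias is emulated by non-uniform
  effort, taxonomic bias by unequal detectability.
* **A trait database** covering a configurable fraction of species, with
  multiplicative intraspecific noise of a given coefficient of variation
  and optional authority-suffix name noise.

What the generator deliberately does **not** emulate: phenology, temporal
dynamics, dispersal limitation, species interactions, real taxonomies
(synonyms beyond authority suffixes), geodetic projections (the world is an
abstract equal-area plane in km), and any quantitative calibration of
occurrence bias to a real data stream. Passing tests therefore demonstrate
that the machinery is correct and that the method behaves as designed under
its own assumptions — not that any particular accuracy will be attained on
real data, whose biases are stronger and less stationary.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `minOcc`, `maxOcc` | 10, 500 | records/cell | density floor and cap for occurrence cells |
| `minPredictorFrac` | 0.6 | fraction | completeness filter; a row at exactly 60% is kept |
| `K`, `nSim` | 5, 100 | — | folds and balance simulations of the spatial blocking |
| hexagon width | fitted range | km | across-flats width; adjacent-cell points of different folds are separated near or beyond the range |
| `nrounds`, `eta`, `maxDepth` | 150, 0.1, 5 | — | modest boosted-tree defaults; learner settings are never tuned by the spatial CV |
| DI threshold | $Q_{75} + 1.5\,\mathrm{IQR}$ | — | outlier rule on the training DI distribution |
| COV $\varepsilon$-guard | $10^{-6}\,|\bar{\mu}|$ | — | masks pixels whose mean prediction is numerically zero |

# Numerical and design choices

* **CWM accounting.** When unmatched species are removed from a plot, the
  remaining covers are renormalized (`renormalize = TRUE`), the standard
  CWM convention; the alternative that keeps unmatched cover in the
  denominator is one switch away, and the matched-cover fraction is always
  reported so the two are comparable.
* **Subsampling order.** The 10–500 rule is applied to *trait-matched*
  records, per cell and per trait table being built, independently at each
  resolution.
* **Fold draws.** Each simulation draws a balanced random partition
  (hexagon counts per fold differ by at most one), so $K$ non-empty folds
  exist whenever there are at least $K$ hexagons; with many hexagons this
  is indistinguishable from i.i.d. assignment while remaining usable on
  desk-scale domains.
* **Pure-nugget fallback.** A flat variogram leaves the range
  unidentifiable; the fit then pins the range to `maxLag` and warns loudly
  rather than failing.
* **Pruning criterion.** Features are dropped when their permutation
  importance on the internal tuning fold is $\le 0$; an importance of
  exactly 0 identifies features the model never split on.
* **COV scale.** Computed on back-transformed (original trait units)
  predictions, where means are bounded away from zero for positive traits;
  the transformed scale can have near-zero means that destabilize
  sd/mean.
* **nRMSE normalization.** By the observed range of the pooled validation
  set; by-mean and by-IQR variants are selectable and the choice is
  recorded in every report.
* **Imputation before DI.** Missing predictor values are imputed (median
  by default; a per-feature boosted-tree imputer mirrors the heavier
  model-based option), fitted on training rows only and applied unchanged
  to new pixels, so the AOA covers the same extent as the predictions.
* **Quantized maps.** Prediction and COV bands are affinely quantized to
  signed 16-bit codes, $\mathrm{scale} = (\max - \min)/(2^{16} - 2)$, with
  a reserved nodata code; the AOA band is stored as 0/1 losslessly.
  Rasters serialize as plain-text Esri ASCII grids with a JSON sidecar
  carrying grid, scales, offsets, $\lambda$ and provenance — a portable,
  diff-able container with the same information content as a multi-band
  GeoTIFF.

# Problem sizes used in the test suite

The package's tests and the acceptance script run the full pipeline on a
40 × 40 km world at 1 km resolution with 30 species, 700 survey plots and
25,000 occurrence records, plus a 200 × 200 grid for variogram recovery
and 2,000-point Gaussian-process simulations for the spherical fit. These
sizes were chosen so that each property is measurable with comfortable
statistical margins while a complete run stays in the seconds-to-minutes
range; the same code paths scale to larger worlds unchanged.

# Known limitations

* The hexagon tessellation is fixed once per fold-building call; the 100
  simulations redraw fold labels only, not the tessellation.
* Variograms are isotropic; anisotropy and kriging are out of scope.
* The DI uses unweighted standardized Euclidean distance; predictor-
  importance weighting of the distance is a known refinement not
  implemented here.
* Model-based imputation fits one regressor per feature on the remaining
  features and is noticeably slower than the median default.
* $R^2$ on pooled pairs can be dominated by across-stratum variance
  differences; it is always reported alongside *r* and nRMSE, never
  alone.

# Reproducing a run

```{r, eval = FALSE}
library(traitmapper)
res <- runPipeline(list(seed = 1), outDir = "run1")
res$metrics
```

Every artifact written to `outDir` (tables, metrics, quantized map
bundles) carries the resolved configuration and seed, and a rerun with the
same configuration produces identical metrics.
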