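---
title: "Models, design choices and validation in ensembleSDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, design choices and validation in ensembleSDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ensembleSDM)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices
made where the design was genuinely open, and the known limitations.

## The analysis in one paragraph

Occurrence records and a stack of bioclimatic rasters go in; what comes
out is, per species and per climate scenario, a binary range map and its
derived quantities: range area and percent change, continuous-suitability
change, stacked species richness, a gap-analysis conservation class, and a
null-model verdict on whether protected areas (PAs) hold more richness
than chance. Every stochastic step takes a seed derived from one master
seed, so a whole run is a pure function of its configuration.

## Climate space

Bioclimatic variables mix units (°C, mm) and are strongly collinear, so
the predictors are principal-component scores rather than raw layers.
We use correlation-matrix PCA (each variable standardized); the number of
retained axes is the smallest *k* whose cumulative explained variance
reaches the `variance_threshold` (default 0.95). Futures are projected
with the *present-day* standardization constants and loadings —
`projectStack()` never refits — so that climate change appears as movement
of cells through a fixed niche space, not as a rotation of the space
itself. Two numerical conventions make results reproducible across linear
algebra backends: each axis' sign is fixed so its largest-magnitude
loading is positive, and nodata cells are excluded from fitting and
projected as nodata. Whether the PCA should be fitted on the full
continental extent or only the study biome is a genuine modelling choice;
`fitPCA()` takes an explicit mask argument and the pipeline fits on the
study mask it models.

## Occurrences, pseudo-absences, and the envelope question

Thinning keeps one record per cell of a grid at twice the predictor
resolution (`thinPoints()`), removing duplicate and clumped records; the
kept record is chosen uniformly at random, and thinning is idempotent
under the same seed. Pseudo-absences are drawn 1:1 with presences.

Where should they be drawn? The phrase "randomized within climatically
suitable areas" admits two readings. Standard environmental-restriction
practice places pseudo-absences *outside* the region the presences define
as suitable, so that the contrast teaches the model what unsuitable
climate looks like; the literal reading places them inside it. We default
to *outside* the presences' rectilinear min–max envelope (computed on the
PCA axes, so restriction and modelling share one space) and expose
`inside = TRUE` for the literal reading. Sampling is uniform without
replacement over eligible cells, never on a presence cell, falling back to
with-replacement with a warning only when eligible cells run short.

## Partitioning

Species with at least 15 presence records (counted after thinning — the
records that actually enter the models) get a checkerboard block design;
smaller species get random 3-fold. The checkerboard block size is chosen
from log-spaced candidates between twice the predictor resolution and 10
map units by three criteria, each computed on the induced two-fold split:

* Moran's *I* of the presence/absence label, inverse-distance weights
  truncated at five block sizes — lower is better (less spatial
  autocorrelation between folds). The variable *I* is computed on is not
  canonical; the label is the quantity whose independence between folds
  matters for evaluation.
* Euclidean distance between the two folds' centroids in standardized
  predictor space — lower is better (environmentally similar folds).
* Standard deviation of per-fold record counts — lower is better.

The three ranks are combined by an unweighted rank sum ("simultaneous"
consideration with no stated weighting is most faithfully an equal-weight
rank aggregation), ties break to the smallest block. Candidates that leave
a fold empty are invalid; if all are, the error suggests k-fold.

## The five algorithms

All are fitted on presence/pseudo-absence points in axis space with fixed,
untuned hyperparameters (no tuning is part of the design; tuning would
also leak across folds):

| id | model | notes |
|----|-------|-------|
| `glm` | binomial GLM, linear + quadratic terms | quadratic terms allow unimodal responses |
| `maxent_like` | ridge-penalized logistic (λ = 0.01), presences vs 1,000 uniform background cells, linear + quadratic features | the penalized-logistic equivalent of maximum entropy; for a Gaussian niche the log-odds truly are quadratic, so this model is correctly specified |
| `rf` | random forest, 500 trees | |
| `svm` | RBF-kernel SVM with Platt-scaled probabilities | |
| `gau` | Gaussian-process classifier, RBF kernel, median-heuristic width | |

Per training fold, each algorithm is fitted on the complement and its
prediction map computed; per-algorithm maps are the mean over folds of the
*continuous* maps (averaging before thresholding keeps the ensemble map
continuous and avoids committing to per-fold thresholds fitted on less
data). Predictions are clamped to [0, 1] and nodata propagates.

## Evaluation, ensemble, threshold

Test-fold predictions are scored by the Jaccard index at the max-Jaccard
threshold and by rank-based AUC (the normalized Mann–Whitney statistic;
ties count one half). The ensemble uses the "above-mean" rule: the
selection score is each algorithm's mean test Jaccard (the analysis'
headline evaluation metric; the score being averaged is otherwise
unstated), the cutoff is the plain mean of those scores, members are the
algorithms strictly above it (all of them if none is, e.g. all equal), and
the ensemble map is the unweighted mean of member maps — weighted variants
were deliberately not implemented absent any stated weighting rule.

The species-specific binarization threshold maximizes Jaccard of the
ensemble suitability against all evaluation points, scanning the unique
observed scores; ties break to the lowest threshold (the most inclusive
range among equally good cutoffs). Future maps reuse the present-day
threshold: the future has no test data, and re-deriving a threshold there
would conflate climate change with threshold drift.

## Range dynamics

Binary ranges are masked to the five permitted broadleaf tree/shrub cover
classes, each scenario with its own land-cover raster. Percent area change
classifies species with a strict ±5% stability band (|Δ| < 5% is stable —
"less than", so exactly 5% is a gain/loss). Suitability change has no
canonical definition; we declare it as the domain-wide percent change in
summed ensemble suitability (default) with a mean-within-present-range
alternative behind the `statistic` argument. Cell areas are uniform on
synthetic grids and cosine-latitude-weighted on geographic (degree) grids.
Richness is the cell-wise sum of binary maps and conserves them exactly.

## Protected-area effectiveness

PAs are clipped to the biome mask first, then dropped below 50 km² —
order matters and is tested. The representation target is 100% of range
below 1,000 km², 10% above 250,000 km², log-linear between (the base of
the logarithm cancels). Attainment (achieved/target) classifies species at
90/70/20% into P/PP/G/NP. Overlapping PAs are counted by union semantics.

The null model relocates a PA's exact cell footprint (no rotation or
reflection — size, shape, orientation preserved) uniformly among all
placements that fit inside the domain, and compares observed mean per-cell
richness with the null distribution; `p = (1 + #{null ≥ observed})/(n+1)`
with n = 999 replicates, effective iff p < 0.05 ("95% above chance" read
as the 95th null percentile; the arithmetic reading — observed ≥ 1.95× the
null mean — is noted but not implemented). Two numerical choices matter:

* The null draws exclude the PA's own placement (unless it is the only
  valid one): the null hypothesis describes *alternative* placements, and
  including the observed one would make the extreme case (a PA exactly on
  the unique richness hotspot) yield p > 1/(n+1) purely through
  self-collisions of the sampler.
* The statistic is the *mean* per-cell richness (robust to PA size); the
  summed variant is available by flag. Tests are reported per PA; a
  network-level reading aggregates the per-PA verdicts.

On structureless richness the per-PA p-values are near-uniform, so the
type-I error at α = 0.05 stays ≈ 5% — verified by simulation over 500
random footprints in the test suite.

## The synthetic generator: what it emulates, and what it does not

The generator exists so that every stage has inputs with the statistical
structure the analysis assumes, plus ground truth:

* **Climate.** Each layer is white noise smoothed by a Gaussian kernel
  (width `spatial_range`, default 5 cells) and re-standardized — simpler
  than variogram-based simulation and sufficient to produce the smooth,
  autocorrelated fields that make spatial blocking meaningful. Layers are
  mixed by the Cholesky factor of a target correlation matrix; the default
  is a three-factor structure (loadings 0.85/0.2, unit diagonal) emulating
  the temperature/precipitation/seasonality blocks of real bioclim sets —
  under it, 19 layers compress to ~6–7 axes at the 95% rule, as real data
  do. Layers are then scaled to bioclim-like units so that the
  correlation-PCA choice is exercised.
* **Futures.** Per-variable additive (temperature-style) and
  multiplicative (precipitation-style) shifts, two pathways × five models
  with a deterministic per-model spread, mimicking inter-AOGCM
  disagreement.
* **Species.** Gaussian niches on the first two climate layers; optima at
  the landscape mean ± 0.5 SD (direction alternating across species),
  breadth = 1 landscape SD — intermediate-prevalence virtual species of
  the kind the virtual-species literature simulates. Presences are sampled
  with probability proportional to suitability at cell centers.
* **True range.** Defined as cells with suitability ≥
  `prevalence_threshold`, default 0.1. The low default is a coherence
  requirement, not a convenience: because records are sampled proportional
  to suitability *everywhere*, a high cutoff would define a "true range"
  that excludes a substantial share of the species' own occurrences
  (at 0.5, roughly a quarter of records fall outside it), making range
  recovery ill-posed as a target. At 0.1 the range contains essentially
  all occurrence mass while still excluding the unsuitable tail.
* **Protected areas.** Footprints grow by random accretion of frontier
  cells from a random seed cell, guaranteeing connectedness; sizes uniform
  in `size_range`; categories drawn from the three Amazonian classes
  (integral protection, sustainable use, indigenous lands).
* **Land cover.** Class probabilities vary smoothly with the first climate
  layer; hot cells lose forest, so warmer scenarios convert permitted
  classes to open ones monotonically. Future land cover must be generated
  against the present-day standardization (`reference` argument),
  otherwise the shift would cancel.

What it does **not** emulate: taxonomic and georeferencing error,
sampling bias toward roads and rivers, dispersal limits, biotic
interactions, non-Gaussian (skewed, bimodal, interacting) niches, and the
spatially complex geometry of real biomes and PA systems. Passing the
recovery tests therefore shows the chain is implemented correctly and is
statistically capable under its own assumptions — not that any real
species' range is this recoverable.

## Validation against ground truth

`recoveryExperiment()` runs the full present-day chain on a 60×60
landscape with 3 virtual species and 200 presences each, and measures the
Jaccard overlap between the ensemble binary range and the true range. The
acceptance suite requires a median ≥ 0.7 over 10 seeds (observed ≈ 0.80)
and exact richness conservation. Problem sizes throughout the test suite
(30×30–60×60 grids, 80–200 presences, 49–999 null replicates, 500
footprints for the type-I simulation) were chosen as the smallest at which
the statistical properties under test are stable.

## Known limitations

* The MaxEnt analogue is the penalized-logistic equivalent, not a feature
  classes + regularization-path reimplementation.
* No dispersal constraints: future ranges are climate-and-cover overlays.
* No variable pruning besides PCA; no TSS/Boyce metrics; no
  MESS/extrapolation diagnostics (predictions are clamped instead).
* The raster container is deliberately minimal (single CRS-less grid,
  co-registration required); reprojection and resampling are out of scope.
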