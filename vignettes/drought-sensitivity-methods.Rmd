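---
title: "Methods: quantifying and attributing vegetation drought sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and attributing vegetation drought sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtsense)
```

# The problem

Regional assessments of how vegetation responds to drought compare a
remotely sensed greenness index — here summer (June–August) mean Enhanced
Vegetation Index (EVI), a proxy for aboveground net primary productivity —
between drought years and climatically ordinary years. `droughtsense`
implements that comparison as a reusable, testable pipeline:

1. **SPEI** — classify each pixel-year into drought classes from the
   standardized precipitation–evapotranspiration index at several
   antecedent timescales;
2. **sensitivity** — compute the drought-sensitivity statistic S′ per
   pixel;
3. **screening** — exclude pixels contaminated by disturbance or
   long-term greening/browning trends, and compute cumulative drought
   exposure;
4. **attribution** — model the spatial pattern of S′ as a function of
   landscape predictors with bootstrapped boosted regression trees (BRTs);
5. **reporting** — biome- and ecosystem-level summaries.

A synthetic-data module generates landscapes, climates, and EVI series
with *known injected* sensitivities, disturbances, and trends, so every
stage can be verified against ground truth without any satellite or
climate-archive downloads.

# The drought-sensitivity statistic

For a pixel and an SPEI timescale $k$, let $B_k$ be the set of years with
$-1 < \mathrm{SPEI}_k < 1$ (*baseline*: neither drought nor pluvial), and
$D_k$ the set of years in a drought class. With $\bar E(\cdot)$ the mean
summer EVI over a year set,

$$ S'_k \;=\; 100 \cdot
   \frac{\bar E(B_k) - \bar E(D_k)}{\bar E(B_k)} , $$

the percent decrease of EVI under drought relative to baseline. The
statistic is computed separately for moderate drought
($-1.5 < \mathrm{SPEI} \le -1$) and severe drought
($\mathrm{SPEI} \le -1.5$), for each timescale (3, 6, and 12 months,
ending in August: summer, winter-through-summer, and the entire previous
year), and the reported S′ is the **maximum across timescales** — a pixel
is as sensitive as its most responsive drought timescale. Negative values
(greening under drought) are retained, not truncated.

Ties at the class thresholds go to the dry side, and pluvial years
($\mathrm{SPEI} \ge 1$) form their own class: they are excluded from both
the baseline and the drought-year means, so wet extremes never
contaminate the contrast.

## Design choices that were genuinely open

* **Baseline per timescale.** Each timescale uses its own baseline-year
  set, since the per-timescale S′ is formed before the maximum. A shared
  baseline (years that are baseline at *every* timescale) is available via
  `sensitivity_config(shared_baseline = TRUE)`; with three timescales it
  discards more years and makes the denominator noisier, which is why the
  per-timescale baseline is the default.
* **Central tendency.** Arithmetic mean for both numerator and
  denominator; the median is available by configuration.
* **Minimum year counts.** `min_baseline_years = 3` and
  `min_drought_years = 1`. A 17-year EVI window rarely contains more than
  a couple of years per drought class at a given timescale, so stricter
  drought minima would discard most of the map; both are configurable and
  validity flags propagate into all downstream stages.

# SPEI computation

The monthly climatic water balance is $D = P - \mathrm{PET}$ (PET is an
input; no Thornthwaite/Penman computation is attempted). For each
timescale $k$ the balance is summed over the $k$ months ending in the
anchor month (August by default, so the 3-month window covers the
June–August EVI season), giving one value per pixel-year.

Standardization fits a 3-parameter log-logistic distribution by unbiased
probability-weighted moments ($w_s = E[X(1-F)^s]$, estimated with exact
combinatorial weights) over the calibration period and maps the fitted
CDF through the inverse standard normal. The calibration period defaults
to the pixel's full record. When the moment equations have no admissible
solution (the shape parameter must exceed 1), the implementation falls
back — with a warning — to the empirical method: Gringorten plotting
positions $(r - 0.44)/(n + 0.12)$ through the inverse normal. Both
methods are monotone in the aggregated balance, and on simulated records
they agree to well within 0.15 SPEI units (median absolute difference;
see `test-spei.R`).

A zero-variance balance series is an error, not a silent degenerate
answer. Records shorter than 20 calibration years trigger a warning.

# Screening

Long-term trends are detected with the Mann–Kendall test
($S = \sum_{i<j} \mathrm{sign}(x_j - x_i)$, tie-corrected variance,
±1 continuity correction, two-sided normal p-value) with the Sen slope
(median pairwise slope) as the effect size; robust and standard for short
annual series. The default significance level is 0.05. Disturbance comes
from an input mask (the truth table in synthetic mode) — no change-point
detection is attempted. Exclusions are attributed to the first matching
rule in the order *disturbed → trending → landcover*, so ledger counts
add up to the pixel total.

Cumulative drought exposure is the percent of years 1990–2016 whose
12-month August-anchored SPEI is ≤ −1 (any drought); period, timescale,
and cutoff are configurable.

# Attribution with boosted regression trees

The BRT engine is authored in C++ inside the package, following the
classic ecology BRT protocol:

* squared-error stagewise boosting; each stage fits a best-first
  regression tree with `tree_complexity = 5` splits (6 terminal nodes) to
  the current residuals on a `bag_fraction = 0.5` random subsample, and
  predictions move by `learning_rate` times the tree's output;
* categorical predictors split by **level subsets** (levels ordered by
  within-node mean, then scanned — optimal for squared error), so a
  factor such as ecosystem type accrues influence as a single variable
  rather than as one-hot fragments;
* the number of trees is chosen by **stepwise cross validation**
  (`brt_step()`): trees are added 50 at a time to ten fold-models, the
  pooled out-of-fold squared-error deviance is recorded per step, and
  stepping stops after the minimum has not improved for five consecutive
  steps;
* **relative influence** is Friedman-style: each executed split's
  empirical error reduction accrues to its variable, normalized to sum
  to 100;
* **partial dependence** of a predictor is the average model prediction
  over a reference sample with that predictor fixed at each grid value;
  because tree ensembles are unstable at predictor extremes, curves carry
  5th/95th-percentile trim marks and interpretation should stay between
  them;
* fit statistics are the Pearson correlation between pooled out-of-fold
  predictions and the observed response (`cv_correlation`) and the
  percent of null deviance explained out-of-fold.

The ensemble protocol (`brt_ensemble()`) repeats the whole procedure 20
times on random samples of 10,000 pixels drawn **without replacement**
with distinct derived seeds, and reports medians and interquartile ranges
of influence and fit statistics plus grid-aligned mean partial-dependence
curves. Four independent models are fit by default: each combination of
drought intensity (S′~mod~, S′~sev~) and biome (forest, shrub-steppe).
Predictors whose median influence falls below 5% in a preliminary
all-predictor ensemble are pruned (`prune_predictors()`).

## Numerical choices

* Split search uses histogram binning with up to 1,024 quantile bins per
  numeric column; with ≤ 1,024 distinct values the search is exact.
  Thresholds are stored as actual data values with an `x <= t` left
  convention, so prediction never re-bins.
* Minimum terminal-node size defaults to 10 rows.
* The learning rate defaults to 0.005, chosen so CV-selected tree counts
  exceed 1,000 on reference synthetic datasets of a few thousand rows,
  per standard BRT practice. The package's own verification runs use
  faster settings (0.05–0.1 with a few hundred trees): tree-count budget
  and learning rate trade off one-for-one and the recovered structure is
  the same, which is what those runs check.
* Unseen categorical levels at prediction time map to the majority child
  of each split, with a warning.
* Bagging draws come from R's RNG, so every fit is bit-reproducible under
  `set.seed()` / the `seed` field of `brt_params()`.

# The synthetic-data generator

The generator emulates the *statistical endpoints* the analysis consumes,
not the physics behind them:

* **Landscape** — each covariate (elevation, AET, climatic water deficit,
  soil AWC, soil bulk density, water-table depth, CTI, HLI) is spatially
  smoothed white noise (separable moving average, half-width
  `smoothing_length`) rescaled into configurable natural-unit ranges.
  Moving-average smoothing was chosen over variogram-based simulation
  because it is simple, seedable, and sufficient for predictor-recovery
  tests. Each pixel carries a configurable 33×33 subgrid of HLI,
  landcover, and CTI values, aggregated exactly as the 30-m → 1-km
  products are: shade density = percent of subcells with HLI ≤ 0.6,
  majority landcover, mean CTI. Biomes follow a water-deficit threshold
  (shrub-steppe above 400 mm by default) with elevation-defined
  ecosystems inside each biome.
* **Truth** — true moderate sensitivity is a clipped linear function of
  z-scored covariates, `clip(b0 + Σ b_j z_j, 0, 0.5)`, with elevation and
  soil bulk density the dominant drivers by default; severe sensitivity
  is `clip(1.3 s_mod + 0.02, s_mod, 0.6)`. About 5% of pixels receive a
  permanent 40% EVI step drop at a uniform-random year (disturbance) and
  5% an additive linear drift of 0.01 EVI/yr (trend) — a slope the
  configured Mann–Kendall screen detects reliably at 17 years.
* **Climate** — monthly precipitation from a seasonal gamma model (wet
  winters, dry summers), PET from a July-peaked sinusoid with noise.
  Region-wide droughts are injected by scaling the precipitation of the
  12 months ending in August of named years (defaults: 2001, 2005, 2012,
  2015 with factors 0.70, 0.60, 0.75, 0.50), so pixels share drought
  years the way a real region does and each pixel has both moderate and
  severe years inside the 2000–2016 EVI window.
* **EVI** — `EVI = baseline × (1 − s) × exp(ε)` with `s` selected by the
  drought class of the year at the pixel's true timescale and
  multiplicative log-normal noise (keeps EVI positive and mimics
  proportional greenness variability).

What the generator does **not** emulate: MODIS compositing and QA
filtering, phenology, spatial reprojection, radiative transfer, real
disturbance processes. Tests passing on synthetic data therefore
demonstrate that the *pipeline arithmetic and inference machinery* are
correct and well calibrated — not that any particular real-world
conclusion holds.

# Verification problem sizes

The package's test suite and `scripts/acceptance.R` verify, at sizes
chosen to keep a desk-scale run comfortable:

* SPEI calibration on 1,000 pixels × 60 stationary years (mean ≈ 0,
  sd ≈ 1, severe-class frequency near the normal tail value 0.067);
* exact S′ recovery (noise 0, single timescale) on 200 pixels to machine
  precision, and noisy multi-timescale recovery (noise sd 0.02, 500
  pixels) with median bias inside [0, 2] percentage points — the maximum
  across timescales has a small non-negative selection bias, which the
  test bounds rather than pretends away;
* Mann–Kendall power ≥ 90% against the injected 0.01 EVI/yr trend and a
  false-positive rate near the nominal level, plus exact agreement of S,
  Var(S), and the Sen slope with a brute-force double loop;
* attribution recovery on a 100×100-pixel landscape (10,000 pixels, true
  signal share 0.6): the two true drivers carry the majority of relative
  influence, CV correlation clears 0.5, the elevation partial-dependence
  curve is monotone over the trimmed range, and the no-signal HLI-like
  and shade-density-like predictors are pruned at the 5% threshold in
  replicate ensembles.

# Known limitations

* PET is an input; users with temperature-only data need an external PET
  step.
* CV folds are random, not spatially blocked; with strong spatial
  autocorrelation the CV statistics are optimistic, as they are in the
  standard protocol this package follows.
* The empirical SPEI method clamps values outside the calibration range
  to the extreme plotting positions, compressing tail behaviour when the
  calibration window is short.
* Climate tables are CSV (one row per pixel-month); gridded NetCDF input
  is not supported.
* No interaction-strength statistics or boosting variants (quantile
  loss, dropout); no cartographic output.
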