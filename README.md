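# droughtsense

Quantify the **drought sensitivity of vegetation** from annual
growing-season greenness and attribute its spatial pattern to landscape
characteristics.

`droughtsense` is for landscape ecologists and remote-sensing analysts who
want to ask, at a regional scale: *how much does vegetation greenness drop
in drought years, and which topographic, soil, and climate settings make
places more or less sensitive?* It implements the full chain — drought
classification, the sensitivity statistic, contamination screening,
machine-learning attribution, and summary reporting — together with a
synthetic-data module that injects *known* sensitivities so every stage is
verifiable against ground truth.

## The statistic at the core

For a pixel and an SPEI timescale *k* (3, 6, 12 months ending in August),
let *B* be the years with −1 < SPEI < 1 (baseline: non-drought,
non-pluvial) and *D* the years in a drought class (moderate:
−1.5 < SPEI ≤ −1; severe: SPEI ≤ −1.5). With Ē(·) the mean summer EVI
over a year set,

> S′ₖ = 100 · (Ē(B) − Ē(D)) / Ē(B)

is the percent decrease of EVI under drought relative to baseline, and
the reported sensitivity **S′ = maxₖ S′ₖ** is the maximum across
timescales. S′ is computed separately for moderate and severe drought.
SPEI itself is the k-month climatic water balance (P − PET) standardized
through a PWM-fitted log-logistic distribution.

The spatial pattern of S′ is then modeled with **boosted regression
trees** (tree complexity 5, bag fraction 0.5, stepwise tenfold-CV tree
selection, 20 bootstrapped runs of 10,000 pixels), summarized by relative
influence and partial-dependence curves, with low-influence predictors
pruned at a 5% median-influence threshold.

## Worked example

```r
library(droughtsense)

# a 1,000-pixel synthetic landscape with known injected sensitivities
px   <- simulate_landscape(landscape_config(n_rows = 40, n_cols = 25, seed = 1))$pixels
tru  <- simulate_truth(px, seed = 2)
cl   <- simulate_climate(px$pixel_id, 1985:2016, seed = 3)
spei <- suppressWarnings(compute_spei(cl, spei_config()))
evi  <- simulate_evi(tru, spei, 2000:2016, noise_sd = 0.02, seed = 4)

sens   <- sensitivity_table(evi, spei)          # S' per pixel
trends <- trend_screen(evi)                     # Mann-Kendall screen
scr    <- apply_exclusions(px, tru$disturbed_flag, trends$trend_flag)
scr$ledger
#> disturbed  trending landcover  retained     total
#>        52        69         0       879      1000
```

52 pixels are dropped as disturbed and 69 as trending (first-matching-rule
attribution), leaving 879 of 1,000. Biome-level summaries of the retained,
valid pixels:

```r
keep <- sens$pixel_id %in% scr$retained$pixel_id & sens$valid_mod & sens$valid_sev
biome_summary(sens[keep, ], px$biome[keep])
#>          biome n_pixels median_s_mod median_s_sev spearman_mod_sev frac_sev_gt_mod
#> 1 shrub-steppe      654    10.870831     15.62916        0.7473545       0.8746177
#> 2       forest      223     9.692983     13.04127        0.8402845       0.8161435
```

Median EVI loss is ~10.9% under moderate and ~15.6% under severe drought
in shrub-steppe (9.7% / 13.0% in forest); moderate- and severe-drought
sensitivities are strongly rank-correlated, and severe exceeds moderate in
most pixels — the qualitative structure the generator injected. A BRT fit
then recovers the drivers:

```r
d <- merge(scr$retained, sens[c("pixel_id", "s_mod_max", "valid_mod")])
fit <- brt_step(s_mod_max ~ elev + soil_bd + deficit + aet + cti,
                data = d[d$valid_mod, ],
                params = brt_params(learning_rate = 0.05, max_trees = 500,
                                    step_size = 25, cv_folds = 5, seed = 5))
fit
#> Boosted regression trees (squared-error loss)
#>   trees: 125  tree complexity: 5  learning rate: 0.05  bag fraction: 0.5
#>   CV-selected trees: 125  cv correlation: 0.860  deviance explained: 73.9%
#>   top influences: elev 54.2%, soil_bd 34.5%, deficit 6.7%
```

Elevation and soil bulk density — the two covariates the truth table
actually uses — carry ~89% of the relative influence. `plot(fit, "elev",
ref_data = d)` draws the partial-dependence curve with 5th/95th-percentile
trim marks; `brt_ensemble()` runs the bootstrapped multi-run protocol and
`prune_predictors()` the parsimony step; `run_pipeline(pipeline_config())`
executes the whole chain and writes every stage table plus a JSON
manifest.

See `vignettes/drought-sensitivity-methods.Rmd` for the model, its
assumptions, and all tunable parameters.

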