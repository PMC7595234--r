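# Shared small fixtures, built once per test run.

# a 10 x 10 landscape with subgrids kept for aggregation checks
fix_landscape <- simulate_landscape(
  landscape_config(n_rows = 10, n_cols = 10, subgrid_size = 7, seed = 42),
  subgrids = TRUE)
fix_px <- fix_landscape$pixels

# clean truth (no disturbance / trend contamination)
fix_truth <- local({
  tr <- simulate_truth(fix_px, seed = 7)
  tr$disturbed_flag <- FALSE
  tr$trend_flag <- FALSE
  tr
})

fix_climate <- simulate_climate(fix_px$pixel_id, 1985:2016, seed = 3)
fix_spei <- suppressWarnings(compute_spei(fix_climate))

# noiseless EVI with a single known timescale, for exact-recovery checks
fix_truth6 <- within(fix_truth, true_timescale <- 6L)
fix_evi0 <- simulate_evi(fix_truth6, fix_spei, 2000:2016, noise_sd = 0,
                         seed = 5)

# quick BRT parameter sets for tests
fast_params <- function(...) {
  brt_params(learning_rate = 0.1, max_trees = 300, step_size = 25,
             cv_folds = 5, tree_complexity = 3, min_obs = 5, patience = 3,
             ...)
}

# brute-force Mann-Kendall oracle: plain double loops
mk_oracle <- function(x) {
  n <- length(x)
  S <- 0
  slopes <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    S <- S + sign(x[j] - x[i])
    slopes <- c(slopes, (x[j] - x[i]) / (j - i))
  }
  tie_tab <- table(x)
  tt <- tie_tab[tie_tab > 1]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(tt * (tt - 1) * (2 * tt + 5))) / 18
  list(S = S, var_S = varS, sen = median(slopes))
}
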