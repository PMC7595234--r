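test_that("landscape generation is bit-reproducible and respects ranges", {
  cfg <- landscape_config(n_rows = 8, n_cols = 9, smoothing_length = 0,
                          subgrid_size = 5, seed = 99)
  a <- simulate_landscape(cfg)
  b <- simulate_landscape(cfg)
  expect_identical(a$pixels, b$pixels)
  for (nm in names(cfg$covariate_ranges)) {
    r <- cfg$covariate_ranges[[nm]]
    if (nm == "cti") next  # pixel CTI is redefined as the subgrid mean
    expect_true(all(a$pixels[[nm]] >= r[1] & a$pixels[[nm]] <= r[2]),
                info = nm)
  }
})

test_that("biome rule assigns shrub-steppe above the deficit threshold", {
  thr <- landscape_config()$biome_rule$deficit_threshold
  expect_true(all((fix_px$deficit > thr) ==
                    (fix_px$biome == "shrub-steppe")))
  # exactly one biome and one ecosystem per pixel
  expect_true(all(fix_px$biome %in% c("forest", "shrub-steppe")))
  expect_true(all(nchar(fix_px$ecosystem) > 0))
})

test_that("smoothing induces spatial autocorrelation in covariates", {
  adj_cor <- function(L, seed) {
    cfg <- landscape_config(n_rows = 25, n_cols = 25, smoothing_length = L,
                            subgrid_size = 1, seed = seed)
    px <- simulate_landscape(cfg)$pixels
    f <- matrix(px$elev[order(px$col, px$row)], 25, 25)
    cor(as.numeric(f[-25, ]), as.numeric(f[-1, ]))
  }
  c5 <- mean(vapply(1:10, function(s) adj_cor(5, s), 0))
  c0 <- mean(vapply(1:10, function(s) adj_cor(0, s + 100), 0))
  expect_gt(c5, c0 + 0.3)
})

test_that("subgrid aggregation matches a brute-force loop", {
  set.seed(31)
  for (rep in 1:100) {
    s <- sample(2:8, 1)
    h <- matrix(runif(s * s, 0, 1.2), s, s)
    lc <- matrix(sample(1:4, s * s, replace = TRUE), s, s)
    ct <- matrix(rnorm(s * s, 8, 2), s, s)
    got <- aggregate_subgrid(h, lc, ct)
    # brute force
    n_shade <- 0
    for (i in 1:s) for (j in 1:s) if (h[i, j] <= 0.6) n_shade <- n_shade + 1
    counts <- sapply(1:4, function(k) sum(lc == k))
    expect_equal(got$shade_dens, 100 * n_shade / (s * s))
    expect_equal(got$landcover, which.max(counts))
    expect_equal(got$cti, mean(ct))
  }
})

test_that("shade density uses HLI <= 0.6 with the boundary included", {
  s <- matrix(0.5, 4, 4)
  expect_equal(aggregate_subgrid(s, s * 0 + 1, s)$shade_dens, 100)
  s61 <- matrix(0.61, 4, 4)
  expect_equal(aggregate_subgrid(s61, s61 * 0 + 1, s61)$shade_dens, 0)
  s60 <- matrix(0.6, 4, 4)
  expect_equal(aggregate_subgrid(s60, s60 * 0 + 1, s60)$shade_dens, 100)
})

test_that("majority landcover is a strict count winner", {
  lc <- matrix(c(rep(1, 500), rep(2, 589)), 33, 33)
  h <- matrix(1, 33, 33)
  expect_equal(aggregate_subgrid(h, lc, h)$landcover, 2L)
  expect_error(aggregate_subgrid(matrix(0, 0, 0), matrix(0, 0, 0),
                                 matrix(0, 0, 0)), "empty")
})

test_that("configuration validation rejects bad ranges", {
  expect_error(landscape_config(covariate_ranges = list(
    elev = c(10, 5), aet = c(1, 2), deficit = c(0, 1),
    soil_awc = c(0, 1), soil_bd = c(1, 2), wtd = c(0, 1),
    cti = c(0, 1), hli = c(0, 1))), "elev")
})

test_that("truth table respects sensitivity ordering and drivers", {
  expect_true(all(fix_truth$s_sev_true >= fix_truth$s_mod_true))
  expect_true(all(fix_truth$s_mod_true >= 0))
  expect_true(all(fix_truth$baseline_evi_true > 0 &
                    fix_truth$baseline_evi_true < 1))
  # elevation is a dominant positive driver of true sensitivity
  expect_gt(cor(fix_px$elev, fix_truth$s_mod_true), 0.3)
  expect_gt(cor(fix_px$soil_bd, fix_truth$s_mod_true), 0.2)
})

test_that("attribution data generator hits the target signal share", {
  d <- simulate_attribution_data(30, 30, r2 = 0.6, seed = 12)
  r2_real <- var(d$s_true) / var(d$s_mod_max)
  expect_gt(r2_real, 0.5)
  expect_lt(r2_real, 0.7)
  expect_identical(d, simulate_attribution_data(30, 30, r2 = 0.6, seed = 12))
})
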