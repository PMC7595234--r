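test_that("Mann-Kendall handles monotone and constant series", {
  r <- mann_kendall(1:10)
  expect_equal(r$S, 45)  # all C(10,2) pairs concordant
  expect_gt(r$Z, 0)
  expect_true(r$trend_flag)
  rc <- mann_kendall(rep(2, 10))
  expect_equal(rc$S, 0)
  expect_false(rc$trend_flag)
  expect_error(mann_kendall(1:5), "8 years")
})

test_that("Mann-Kendall statistics match the brute-force oracle", {
  set.seed(60)
  for (rep in 1:100) {
    n <- sample(8:17, 1)
    x <- round(rnorm(n, 0.5, 0.1), sample(1:3, 1))  # rounding makes ties
    got <- mann_kendall(x)
    want <- mk_oracle(x)
    expect_equal(got$S, want$S)
    expect_equal(got$var_S, want$var_S)
    expect_equal(got$sen_slope, want$sen)
  }
})

test_that("trend screening flags strong trends and spares nulls", {
  set.seed(61)
  hits <- replicate(100, mann_kendall(0.4 + 0.01 * (0:16) +
                                        rnorm(17, 0, 0.02))$trend_flag)
  expect_gte(mean(hits), 0.9)
  nulls <- replicate(200, mann_kendall(0.4 + rnorm(17, 0, 0.02))$trend_flag)
  expect_lte(mean(nulls), 1.5 * 0.05 + 0.03)
})

test_that("trend_screen applies the test per pixel", {
  yrs <- 2000:2016
  evi <- rbind(
    data.frame(pixel_id = 1, year = yrs, evi_summer = 0.4 + 0.012 * (0:16)),
    data.frame(pixel_id = 2, year = yrs,
               evi_summer = 0.4 + c(0.01, -0.01)[1 + (0:16) %% 2]))
  ts <- trend_screen(evi)
  expect_true(ts$trend_flag[ts$pixel_id == 1])
  expect_false(ts$trend_flag[ts$pixel_id == 2])
  expect_equal(ts$sen_slope[1], 0.012, tolerance = 1e-10)
})

test_that("exclusions attribute pixels to the first matching rule", {
  px <- data.frame(pixel_id = 1:6,
                   ecosystem = c("a", "a", "b", "b", "c", "c"))
  r <- apply_exclusions(px, disturbed_flag = rep(FALSE, 6),
                        trend_flag = rep(FALSE, 6))
  expect_equal(nrow(r$retained), 6)
  # disturbed and trending counts once under disturbed
  r2 <- apply_exclusions(px,
                         disturbed_flag = c(TRUE, FALSE, FALSE, FALSE,
                                            FALSE, FALSE),
                         trend_flag = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                        FALSE),
                         keep_landcover = c("a", "b"))
  expect_equal(unname(r2$ledger["disturbed"]), 1)
  expect_equal(unname(r2$ledger["trending"]), 1)
  expect_equal(unname(r2$ledger["landcover"]), 2)
  expect_equal(unname(r2$ledger["retained"]), 2)
  # accounting identity
  expect_equal(sum(r2$ledger[c("disturbed", "trending", "landcover",
                               "retained")]),
               unname(r2$ledger["total"]))
  expect_error(apply_exclusions(px, rep(NA, 6), rep(FALSE, 6)), "missing")
  expect_error(apply_exclusions(px, TRUE, rep(FALSE, 6)), "cover")
})

test_that("drought exposure is the percent of years at or below the cutoff", {
  st <- data.frame(pixel_id = 1, year = 1990:2016, timescale = 12,
                   spei = 0.5, drought_class = "baseline")
  expect_equal(drought_exposure(st)$drought_exp, 0)
  st$spei[1:9] <- -1.2
  expect_equal(drought_exposure(st)$drought_exp, 100 * 9 / 27)
  # brute force on random tables; monotone in threshold
  set.seed(62)
  for (rep in 1:50) {
    z <- rnorm(27)
    st$spei <- z
    got <- drought_exposure(st)$drought_exp
    expect_equal(got, 100 * sum(z <= -1) / 27)
    loose <- drought_exposure(st, threshold = -0.5)$drought_exp
    expect_gte(loose, got)
    expect_true(got >= 0 && got <= 100)
  }
  expect_error(drought_exposure(st, period = 1980:2016), "cover")
})
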