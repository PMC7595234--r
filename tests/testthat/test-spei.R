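test_that("water balance is precipitation minus PET with gap checking", {
  cl <- data.frame(pixel_id = 1, year = rep(2000:2001, each = 12),
                   month = rep(1:12, 2), prcp = 50, pet = 80)
  wb <- water_balance(cl)
  expect_equal(wb$d, rep(-30, 24))
  cl$pet <- 0
  expect_equal(water_balance(cl)$d, cl$prcp)
  expect_error(water_balance(cl[-5, ]), "gap")
})

test_that("aggregation sums the k months ending in the anchor month", {
  cl <- data.frame(pixel_id = 1, year = rep(2000:2002, each = 12),
                   month = rep(1:12, 3),
                   prcp = seq_len(36), pet = 0)
  wb <- water_balance(cl)
  ab3 <- aggregate_balance(wb, 3, 8)
  # June + July + August of each year
  expect_equal(ab3$balance,
               c(6 + 7 + 8, 18 + 19 + 20, 30 + 31 + 32))
  cl$prcp <- 0
  cl$pet <- 10
  ab12 <- suppressWarnings(aggregate_balance(water_balance(cl), 12, 8))
  expect_equal(ab12$balance, rep(-120, 2))  # first year lacks history
})

test_that("aggregation matches a brute-force window sum on random series", {
  set.seed(14)
  for (rep in 1:50) {
    ny <- sample(4:8, 1)
    k <- sample(c(3, 6, 12), 1)
    cl <- data.frame(pixel_id = 1, year = rep(2000 + seq_len(ny), each = 12),
                     month = rep(1:12, ny),
                     prcp = runif(12 * ny, 0, 200),
                     pet = runif(12 * ny, 0, 150))
    wb <- water_balance(cl)
    got <- suppressWarnings(aggregate_balance(wb, k, 8))
    d <- wb$d
    for (r in seq_len(nrow(got))) {
      yi <- got$year[r] - 2000
      end <- (yi - 1) * 12 + 8
      expect_equal(got$balance[r], sum(d[(end - k + 1):end]))
    }
  }
})

test_that("empirical standardization is calibrated and monotone", {
  set.seed(2)
  x <- rnorm(60, -100, 40)
  z <- spei_standardize(x, method = "empirical")
  expect_lt(abs(mean(z)), 0.05)
  expect_gt(sd(z), 0.9)
  expect_lt(sd(z), 1.1)
  expect_equal(which.max(z), which.max(x))
  expect_equal(which.min(z), which.min(x))
})

test_that("log-logistic SPEI reproduces normal tail frequencies", {
  set.seed(6)
  x <- rnorm(1000, -50, 30)
  z <- spei_standardize(x, method = "log-logistic")
  expect_lt(abs(mean(z <= -1.5) - 0.067), 0.02)
  expect_lt(abs(mean(z)), 0.05)
  expect_true(all(diff(z[order(x)]) >= 0))  # monotone in the balance
})

test_that("log-logistic and empirical SPEI agree closely", {
  set.seed(41)
  diffs <- replicate(200, {
    x <- rnorm(60, -80, 35)
    zl <- suppressWarnings(spei_standardize(x, method = "log-logistic"))
    ze <- spei_standardize(x, method = "empirical")
    median(abs(zl - ze))
  })
  expect_lt(median(diffs), 0.15)
})

test_that("SPEI is invariant to adding a constant to both P and PET", {
  cl <- simulate_climate(1:3, 1990:2016, seed = 10)
  cl2 <- cl
  cl2$prcp <- cl2$prcp + 37
  cl2$pet <- cl2$pet + 37
  s1 <- suppressWarnings(compute_spei(cl))
  s2 <- suppressWarnings(compute_spei(cl2))
  expect_equal(s1$spei, s2$spei, tolerance = 1e-10)
})

test_that("drought classes honour the printed thresholds and partition", {
  expect_equal(as.character(classify_drought(-1.0)), "moderate")
  expect_equal(as.character(classify_drought(-1.5)), "severe")
  expect_equal(as.character(classify_drought(0)), "baseline")
  expect_equal(as.character(classify_drought(1.0)), "pluvial")
  # exhaustive, mutually exclusive partition over a fine sweep
  z <- seq(-4, 4, by = 0.001)
  cls <- classify_drought(z)
  expect_true(!anyNA(cls))
  expect_equal(sum(cls == "severe"), sum(z <= -1.5))
  expect_equal(sum(cls == "moderate"), sum(z > -1.5 & z <= -1))
  expect_equal(sum(cls == "baseline"), sum(z > -1 & z < 1))
  expect_equal(sum(cls == "pluvial"), sum(z >= 1))
  expect_error(classify_drought(NaN), "finite")
})

test_that("degenerate series and short calibrations are rejected", {
  expect_error(spei_standardize(rep(5, 30)), "zero-variance")
  expect_error(spei_standardize(rnorm(4)), "short")
})
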