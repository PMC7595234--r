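make_class_table <- function(pixel_id, years, classes) {
  data.frame(pixel_id = pixel_id, year = years, timescale = 6,
             spei = 0, drought_class = factor(classes,
               levels = c("pluvial", "baseline", "moderate", "severe")))
}

test_that("baseline EVI is the mean over baseline-class years", {
  yrs <- 2000:2016
  st <- make_class_table(1, yrs, rep("baseline", 17))
  evi <- data.frame(pixel_id = 1, year = yrs, evi_summer = 0.5)
  b <- baseline_evi(evi, st, 6)
  expect_equal(b$baseline_evi, 0.5)
  expect_true(b$valid)
  # too few baseline years -> invalid
  st2 <- make_class_table(1, yrs, c(rep("baseline", 2), rep("severe", 15)))
  evi2 <- evi
  evi2$evi_summer <- c(0.4, 0.6, rep(0.3, 15))
  b2 <- baseline_evi(evi2, st2, 6, min_baseline_years = 3)
  expect_false(b2$valid)
})

test_that("S' follows its defining formula", {
  yrs <- 2000:2016
  cls <- c(rep("baseline", 10), rep("moderate", 7))
  st <- make_class_table(1, yrs, cls)
  evi <- data.frame(pixel_id = 1, year = yrs,
                    evi_summer = c(rep(0.40, 10), rep(0.36, 7)))
  s <- timescale_sensitivity(evi, st, 6, "moderate")
  expect_equal(s$s, 10.0)
  # drought mean equal to baseline mean -> S' = 0
  evi$evi_summer <- 0.4
  expect_equal(timescale_sensitivity(evi, st, 6, "moderate")$s, 0)
})

test_that("baseline and drought means match a brute-force filter", {
  set.seed(50)
  yrs <- 2000:2016
  for (rep in 1:50) {
    cls <- sample(c("pluvial", "baseline", "moderate", "severe"), 17,
                  replace = TRUE, prob = c(0.15, 0.55, 0.2, 0.1))
    ev <- runif(17, 0.2, 0.8)
    st <- make_class_table(1, yrs, cls)
    evi <- data.frame(pixel_id = 1, year = yrs, evi_summer = ev)
    b <- baseline_evi(evi, st, 6)
    bf_base <- mean(ev[cls == "baseline"])
    if (sum(cls == "baseline") >= 3) {
      expect_equal(b$baseline_evi, bf_base)
      if (any(cls == "moderate")) {
        s <- timescale_sensitivity(evi, st, 6, "moderate")
        expect_equal(s$s, 100 * (bf_base - mean(ev[cls == "moderate"])) /
                       bf_base)
      }
    } else {
      expect_false(b$valid)
    }
  }
})

test_that("max across timescales keeps the attaining timescale", {
  r <- max_sensitivity(c(`3` = 4.0, `6` = 7.5, `12` = 6.0))
  expect_equal(r$s_max, 7.5)
  expect_equal(r$timescale, 6L)
  r2 <- max_sensitivity(c(`3` = NA, `6` = NA, `12` = 5.0))
  expect_equal(r2$s_max, 5.0)
  expect_equal(r2$timescale, 12L)
  r3 <- max_sensitivity(c(`3` = NA_real_, `6` = NA_real_))
  expect_false(r3$valid)
})

test_that("noiseless generator output is recovered exactly", {
  sens <- sensitivity_table(fix_evi0, fix_spei,
                            sensitivity_config(timescales = 6))
  ok <- sens$valid_mod
  expect_gt(sum(ok), 80)
  expect_equal(sens$s_mod_max[ok], 100 * fix_truth6$s_mod_true[ok],
               tolerance = 1e-12)
  ok2 <- sens$valid_sev
  expect_equal(sens$s_sev_max[ok2], 100 * fix_truth6$s_sev_true[ok2],
               tolerance = 1e-12)
})

test_that("S' is invariant to rescaling a pixel's EVI series", {
  evi2 <- fix_evi0
  evi2$evi_summer <- evi2$evi_summer * 3.7
  a <- sensitivity_table(fix_evi0, fix_spei)
  b <- sensitivity_table(evi2, fix_spei)
  expect_equal(a$s_mod_max, b$s_mod_max, tolerance = 1e-10)
  expect_equal(a$s_sev_max, b$s_sev_max, tolerance = 1e-10)
})

test_that("the sensitivity table conserves pixels and flags gaps", {
  sens <- sensitivity_table(fix_evi0, fix_spei)
  expect_equal(nrow(sens), length(unique(fix_evi0$pixel_id)))
  ex <- attr(sens, "exclusions")
  expect_equal(unname(ex["n_pixels"]), nrow(sens))
  # pixels without severe years at any timescale must be flagged invalid
  no_sev <- vapply(sens$pixel_id, function(p) {
    st <- fix_spei[fix_spei$pixel_id == p & fix_spei$year %in% 2000:2016, ]
    !any(st$drought_class == "severe")
  }, TRUE)
  expect_true(all(!sens$valid_sev[no_sev]))
  expect_true(all(is.na(sens$s_sev_max[no_sev])))
})
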