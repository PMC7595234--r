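fake_sens <- function(s_mod, s_sev) {
  data.frame(pixel_id = seq_along(s_mod), s_mod_max = s_mod,
             s_sev_max = s_sev, valid_mod = TRUE, valid_sev = TRUE,
             baseline_6 = 0.5)
}

test_that("biome medians and IQRs use linear interpolation", {
  s <- fake_sens(c(1, 2, 3), c(2, 4, 6))
  b <- biome_summary(s, rep("forest", 3))
  expect_equal(b$median_s_mod, 2)
  expect_equal(b$iqr_mod_lo, 1.5)
  expect_equal(b$iqr_mod_hi, 2.5)
  expect_equal(b$spearman_mod_sev, 1)  # strictly monotone pairing
})

test_that("degenerate equal sensitivities are flagged", {
  s <- fake_sens(c(2, 3, 4), c(2, 3, 4))
  b <- biome_summary(s, rep("forest", 3))
  expect_equal(b$frac_sev_gt_mod, 0)
  expect_true(is.na(b$mean_excess_sev))
})

test_that("excess and declining fractions follow their definitions", {
  s <- fake_sens(c(1, 5, -2, 3), c(4, 5, -1, 2))
  b <- biome_summary(s, rep("steppe", 4))
  expect_equal(b$frac_sev_gt_mod, 0.5)   # pixels 1 and 3
  expect_equal(b$mean_excess_sev, mean(c(3, 1)))
  expect_equal(b$frac_declining_mod, 0.75)
  expect_equal(b$frac_declining_sev, 0.75)
})

test_that("empty biomes are omitted with a warning", {
  s <- fake_sens(c(1, 2), c(2, 3))
  s$valid_mod[1] <- FALSE
  expect_warning(b <- biome_summary(s, c("empty", "forest")), "empty")
  expect_equal(nrow(b), 1)
})

test_that("ecosystem medians match a brute-force group-by", {
  set.seed(70)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    eco <- sample(c("cs", "rms", "ts"), n, replace = TRUE)
    s <- fake_sens(rnorm(n, 5, 3), rnorm(n, 8, 4))
    es <- ecosystem_summary(s, eco)
    for (e in unique(eco)) {
      expect_equal(es$summary$median_s_mod[es$summary$ecosystem == e],
                   median(s$s_mod_max[eco == e]))
      expect_equal(es$summary$median_s_sev[es$summary$ecosystem == e],
                   median(s$s_sev_max[eco == e]))
    }
    # assignment table: one row per labeled pixel, medians propagated
    expect_equal(nrow(es$assignment), n)
    i <- match(es$assignment$ecosystem, es$summary$ecosystem)
    expect_equal(es$assignment$median_s_mod, es$summary$median_s_mod[i])
  }
})

test_that("a single ecosystem's median equals the biome median", {
  s <- fake_sens(c(1, 4, 9, 2), c(3, 5, 10, 4))
  es <- ecosystem_summary(s, rep("ws", 4))
  b <- biome_summary(s, rep("forest", 4))
  expect_equal(es$summary$median_s_mod, b$median_s_mod)
})

test_that("the pooled biome median lies within the ecosystem medians", {
  set.seed(71)
  s <- fake_sens(rnorm(200, 6, 2), rnorm(200, 9, 3))
  eco <- sample(c("a", "b", "c"), 200, replace = TRUE)
  es <- ecosystem_summary(s, eco)
  b <- biome_summary(s, rep("forest", 200))
  expect_gte(b$median_s_mod, min(es$summary$median_s_mod))
  expect_lte(b$median_s_mod, max(es$summary$median_s_mod))
})

test_that("unknown ecosystem codes raise an error when codes are fixed", {
  s <- fake_sens(c(1, 2), c(2, 3))
  expect_error(ecosystem_summary(s, c("a", "weird"), codes = "a"),
               "weird")
})

test_that("the 2-D sensitivity histogram conserves pixel counts", {
  set.seed(72)
  s <- fake_sens(rnorm(500, 5, 2), rnorm(500, 8, 3))
  h <- sensitivity_density(s, breaks = 20)
  expect_equal(sum(h$counts), 500)
})
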