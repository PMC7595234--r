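test_that("a single stump reproduces the two group means", {
  x <- data.frame(a = rep(c(-1, 1), each = 25))
  y <- rep(c(5, 10), each = 25)
  fit <- brt(x, y + rnorm(50, 0, 0) ,
             brt_params(tree_complexity = 1, learning_rate = 1,
                        bag_fraction = 1, min_obs = 5, seed = 1),
             n_trees = 1)
  expect_equal(predict(fit), y, tolerance = 1e-12)
  # partial dependence of the stump, balanced reference sample
  pd <- partial_dependence(fit, "a", x, grid_size = 2)
  expect_equal(pd$yhat[pd$value == -1], 5, tolerance = 1e-12)
  expect_equal(pd$yhat[pd$value == 1], 10, tolerance = 1e-12)
})

test_that("boosting predictions are additive in the trees", {
  set.seed(3)
  n <- 200
  x <- data.frame(a = runif(n), b = runif(n))
  y <- sin(6 * x$a) + x$b + rnorm(n, 0, 0.1)
  fit <- brt(x, y, brt_params(tree_complexity = 2, learning_rate = 0.2,
                              bag_fraction = 0.7, min_obs = 5, seed = 4),
             n_trees = 30)
  nd <- x[sample(n, 20), , drop = FALSE]
  lr <- fit$params$learning_rate
  prev <- rep(fit$f0, 20)
  for (k in 1:30) {
    cur <- predict(fit, nd, n_trees = k)
    step_k <- droughtsense:::predict_trees_cpp(
      fit$trees[k], droughtsense:::build_design(nd, names(x))$X,
      fit$design$cat_levels, lr)$pred
    expect_equal(cur, prev + step_k, tolerance = 1e-12)
    prev <- cur
  }
  # the full-model fitted values equal the staged sum
  expect_equal(predict(fit, x, n_trees = 30), fit$fitted,
               tolerance = 1e-12)
})

test_that("training MSE is non-increasing without bagging", {
  set.seed(5)
  n <- 500
  x <- data.frame(a = runif(n), b = runif(n), c = runif(n))
  y <- 2 * x$a - x$b^2 + rnorm(n, 0, 0.2)
  fit <- brt(x, y, brt_params(tree_complexity = 3, learning_rate = 0.3,
                              bag_fraction = 1, min_obs = 10, seed = 6),
             n_trees = 40)
  mse <- vapply(1:40, function(k)
    mean((y - predict(fit, x, n_trees = k))^2), 0)
  expect_true(all(diff(mse) <= 1e-10))
})

test_that("relative influence sums to 100 and isolates lone predictors", {
  set.seed(7)
  n <- 300
  x <- data.frame(elev = runif(n, 0, 3000), noise = runif(n))
  y <- ifelse(x$elev > 1500, 8, 3) + rnorm(n, 0, 0.01)
  fit <- brt(x, y, brt_params(tree_complexity = 1, learning_rate = 0.5,
                              bag_fraction = 1, min_obs = 10, seed = 8),
             n_trees = 10)
  ri <- relative_influence(fit)
  expect_equal(sum(ri), 100, tolerance = 1e-6)
  expect_equal(unname(ri["elev"]), 100, tolerance = 1e-6)
  expect_equal(unname(ri["noise"]), 0, tolerance = 1e-6)
})

test_that("partial dependence is flat for an ignored predictor", {
  set.seed(9)
  n <- 300
  x <- data.frame(a = runif(n), z = runif(n))
  y <- 4 * (x$a > 0.5)  # exactly explained by a; z carries nothing
  fit <- brt(x, y, brt_params(tree_complexity = 1, learning_rate = 0.5,
                              bag_fraction = 1, min_obs = 10, seed = 10),
             n_trees = 20)
  pd <- partial_dependence(fit, "z", x, grid_size = 20)
  expect_lt(diff(range(pd$yhat)), 1e-9)
  expect_true(!is.null(attr(pd, "q5")))
})

test_that("categorical predictors split by level subsets", {
  set.seed(11)
  n <- 400
  x <- data.frame(eco = factor(sample(c("a", "b", "c", "d"), n, TRUE)))
  y <- ifelse(x$eco %in% c("a", "c"), 10, 2) + rnorm(n, 0, 0.01)
  fit <- brt(x, y, brt_params(tree_complexity = 1, learning_rate = 1,
                              bag_fraction = 1, min_obs = 10, seed = 12),
             n_trees = 1)
  pr <- predict(fit, data.frame(eco = factor(c("a", "b", "c", "d"))))
  expect_equal(pr, c(10, 2, 10, 2), tolerance = 0.01)
  # unseen level maps to the majority branch with a warning
  expect_warning(
    pu <- predict(fit, data.frame(eco = factor("zzz"))),
    "unseen")
  expect_true(pu %in% range(pr) | (pu > min(pr) & pu < max(pr)))
})

test_that("stepwise CV selection stops and reports sane statistics", {
  set.seed(13)
  n <- 400
  x <- data.frame(a = runif(n), b = runif(n))
  # strong signal
  y <- 5 * (x$a > 0.5) + rnorm(n, 0, 0.4)
  fit <- brt_step(x, y, fast_params(seed = 14))
  expect_true(fit$n_trees_selected >= 25)
  null_dev <- var(y) * (n - 1) / n
  expect_lt(min(fit$cv_trace$cv_deviance), 0.5 * null_dev)
  expect_gt(fit$cv_correlation, 0.8)
  expect_gt(fit$pct_deviance_explained, 50)
  expect_lte(fit$pct_deviance_explained, 100)
  # trace bookkeeping: selection + patience steps when patience-stopped
  n_steps <- nrow(fit$cv_trace)
  sel_step <- fit$n_trees_selected / fit$params$step_size
  if (n_steps < ceiling(fit$params$max_trees / fit$params$step_size))
    expect_equal(n_steps, sel_step + fit$params$patience)
})

test_that("pure-noise responses select small models near the null deviance", {
  set.seed(15)
  devs <- replicate(5, {
    n <- 300
    x <- data.frame(a = runif(n), b = runif(n))
    y <- rnorm(n)
    fit <- brt_step(x, y, fast_params(seed = sample.int(1000, 1)))
    min(fit$cv_trace$cv_deviance) / var(y)
  })
  expect_true(all(devs > 0.9))   # CV deviance stays near response variance
  expect_true(all(devs < 1.25))
})

test_that("permuted responses give near-zero CV correlation", {
  set.seed(16)
  n <- 300
  x <- data.frame(a = runif(n), b = runif(n))
  y <- 3 * x$a + rnorm(n, 0, 0.3)
  cors <- vapply(1:10, function(i) {
    yp <- sample(y)
    fit <- brt_step(x, yp, fast_params(seed = 100 + i))
    fit$cv_correlation
  }, 0)
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("degenerate inputs are rejected", {
  x <- data.frame(a = runif(50))
  expect_error(brt(x, rep(1, 50)), "constant")
  expect_error(brt(x, c(rep(1, 49), NA)), "missing")
  expect_error(brt(x[1:10, , drop = FALSE], 1:5), "differ")
})
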