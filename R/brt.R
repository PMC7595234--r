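#' Boosted-regression-tree hyperparameters
#'
#' Defaults follow the standard ecology BRT protocol: interaction depth
#' (`tree_complexity`) 5, bag fraction 0.5, tenfold cross validation, trees
#' added in steps of 50 up to 10,000. The learning rate defaults to 0.005
#' so that selected tree counts comfortably exceed 1,000 on datasets of a
#' few thousand rows; raise it (and lower `max_trees`) for quick
#' exploratory fits.
#'
#' @param tree_complexity number of splits per tree (a tree has
#'   `tree_complexity + 1` terminal nodes).
#' @param bag_fraction fraction of rows randomly subsampled (without
#'   replacement) for each tree.
#' @param learning_rate shrinkage applied to each tree's contribution.
#' @param step_size trees added per cross-validation step in [brt_step()].
#' @param max_trees maximum ensemble size.
#' @param cv_folds folds for stepwise selection and fit statistics.
#' @param patience steps without CV improvement before stepping stops.
#' @param min_obs minimum rows in a terminal node.
#' @param seed optional integer seed set before fitting.
#' @return list of class `brt_params`.
#' @export
brt_params <- function(tree_complexity = 5, bag_fraction = 0.5,
                       learning_rate = 0.005, step_size = 50,
                       max_trees = 10000, cv_folds = 10, patience = 5,
                       min_obs = 10, seed = NULL) {
  stopifnot(tree_complexity >= 1, bag_fraction > 0, bag_fraction <= 1,
            learning_rate > 0, step_size >= 1, max_trees >= 1,
            cv_folds >= 2, patience >= 1, min_obs >= 1)
  structure(list(tree_complexity = as.integer(tree_complexity),
                 bag_fraction = bag_fraction,
                 learning_rate = learning_rate,
                 step_size = as.integer(step_size),
                 max_trees = as.integer(max_trees),
                 cv_folds = as.integer(cv_folds),
                 patience = as.integer(patience),
                 min_obs = as.integer(min_obs), seed = seed),
            class = "brt_params")
}

# build the numeric design matrix: numeric predictors pass through, factors
# and characters become 0-based level codes split by level subsets (not
# one-hot, so influence accrues to the single variable)
build_design <- function(data, predictors, levels = NULL) {
  X <- matrix(0, nrow(data), length(predictors),
              dimnames = list(NULL, predictors))
  cat_levels <- integer(length(predictors))
  out_levels <- vector("list", length(predictors))
  names(out_levels) <- predictors
  for (j in seq_along(predictors)) {
    nm <- predictors[j]
    v <- data[[nm]]
    if (is.null(v)) stop("predictor not found in data: ", nm)
    if (is.numeric(v)) {
      if (anyNA(v)) stop("missing values in predictor ", nm)
      X[, j] <- v
    } else {
      v <- as.character(v)
      lv <- if (!is.null(levels)) levels[[nm]] else sort(unique(v))
      if (length(lv) > 52)
        stop("categorical predictor ", nm, " has more than 52 levels")
      code <- match(v, lv) - 1L
      code[is.na(code)] <- length(lv)  # unseen level sentinel
      X[, j] <- code
      cat_levels[j] <- length(lv)
      out_levels[[nm]] <- lv
    }
  }
  list(X = X, cat_levels = cat_levels, levels = out_levels,
       predictors = predictors)
}

new_brt <- function(trees, f0, fitted, influence_raw, design, params, y) {
  structure(list(trees = trees, f0 = f0, fitted = fitted,
                 influence_raw = influence_raw, design = design,
                 params = params, y = y,
                 n_trees = length(trees)),
            class = "brt")
}

#' Fit a boosted regression tree model
#'
#' Stagewise least-squares gradient boosting: each stage fits a best-first
#' regression tree with `tree_complexity` splits to the current residuals
#' on a random `bag_fraction` subsample, and predictions are updated by
#' `learning_rate` times the tree's output. Categorical predictors are
#' handled by level-subset splits. Use [brt_step()] for the
#' cross-validated choice of the number of trees.
#'
#' @param x predictor data.frame, or a formula.
#' @param ... passed between methods.
#' @return an object of class `brt` with [predict.brt()],
#'   [relative_influence()], [partial_dependence()], [summary.brt()] and
#'   [plot.brt()] methods.
#' @export
brt <- function(x, ...) UseMethod("brt")

#' @rdname brt
#' @param formula model formula, e.g. `s_mod_max ~ elev + soil_bd`; the
#'   right-hand side must name columns of `data` (no transformations).
#' @param data data.frame containing response and predictors.
#' @export
brt.formula <- function(formula, data, ...) {
  tm <- stats::terms(formula, data = data)
  predictors <- attr(tm, "term.labels")
  resp <- all.vars(formula)[1]
  brt.default(data[predictors], data[[resp]], ...)
}

#' @rdname brt
#' @param y numeric response vector.
#' @param params a [brt_params()].
#' @param n_trees number of boosting stages to fit (fixed; default 100).
#' @export
brt.default <- function(x, y, params = brt_params(), n_trees = 100, ...) {
  stopifnot(inherits(params, "brt_params"))
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (anyNA(y)) stop("missing values in response")
  if (var(y) == 0) stop("constant response")
  if (!is.null(params$seed)) set.seed(params$seed)
  d <- build_design(x, names(x))
  f0 <- mean(y)
  r <- boost_more_cpp(d$X, d$cat_levels, y, rep(f0, length(y)),
                      as.integer(n_trees), params$tree_complexity,
                      params$learning_rate, params$bag_fraction,
                      params$min_obs)
  new_brt(r$trees, f0, r$pred, r$influence, d, params, y)
}

#' Predict from a fitted BRT
#'
#' @param object a `brt` fit.
#' @param newdata data.frame of predictors; defaults to returning the
#'   training fitted values.
#' @param n_trees use only the first `n_trees` trees (default all).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.brt <- function(object, newdata = NULL, n_trees = NULL, ...) {
  if (is.null(newdata) && is.null(n_trees)) return(object$fitted)
  if (is.null(n_trees)) n_trees <- object$n_trees
  n_trees <- min(n_trees, object$n_trees)
  if (is.null(newdata)) stop("n_trees subsetting requires newdata")
  d <- build_design(newdata, object$design$predictors,
                    levels = object$design$levels)
  r <- predict_trees_cpp(object$trees[seq_len(n_trees)], d$X,
                         object$design$cat_levels,
                         object$params$learning_rate)
  if (r$n_unseen > 0)
    warning(r$n_unseen,
            " unseen categorical level lookups mapped to majority branch")
  object$f0 + r$pred
}

#' Relative influence of predictors
#'
#' Friedman-style importance: each executed split's empirical
#' squared-error reduction accrues to its split variable; totals are
#' summed over all trees and normalized to percentages summing to 100.
#'
#' @param object a `brt` fit or `brt_ensemble`.
#' @param ... unused.
#' @return named numeric vector of percentages (sums to 100), decreasing.
#' @export
relative_influence <- function(object, ...) UseMethod("relative_influence")

#' @rdname relative_influence
#' @export
relative_influence.brt <- function(object, ...) {
  inf <- object$influence_raw
  names(inf) <- object$design$predictors
  tot <- sum(inf)
  if (tot <= 0) {
    warning("zero total split reduction; returning uniform influence")
    inf[] <- 1
    tot <- sum(inf)
  }
  sort(100 * inf / tot, decreasing = TRUE)
}

#' Partial dependence of the model on one predictor
#'
#' For each grid value v, the average model prediction over a reference
#' sample of rows with the predictor set to v (accounting for the average
#' effects of all other predictors). For categorical predictors, per-level
#' averages are returned instead of a grid. Because tree ensembles are
#' unstable at the extreme ends of a predictor, the 5th and 95th
#' percentiles of the predictor are reported (attributes `q5`, `q95`) and
#' interpretation should focus between them.
#'
#' @param object a `brt` fit.
#' @param predictor predictor name.
#' @param grid_size number of grid points (numeric predictors).
#' @param ref_data reference rows (default: the training-sample cache is
#'   not kept, so pass the data used to fit, or any representative table).
#' @param ref_cap maximum reference rows used (default 1000, subsampled
#'   deterministically by even spacing).
#' @return data.frame with columns `value` and `yhat`; attributes `q5`,
#'   `q95` (numeric predictors only).
#' @export
partial_dependence <- function(object, predictor, ref_data,
                               grid_size = 100, ref_cap = 1000) {
  stopifnot(inherits(object, "brt"))
  j <- match(predictor, object$design$predictors)
  if (is.na(j)) stop("not a model predictor: ", predictor)
  d <- build_design(ref_data, object$design$predictors,
                    levels = object$design$levels)
  n <- nrow(d$X)
  if (n > ref_cap) {
    keep <- unique(round(seq(1, n, length.out = ref_cap)))
    d$X <- d$X[keep, , drop = FALSE]
  }
  is_cat <- d$cat_levels[j] > 0
  if (is_cat) {
    lv <- object$design$levels[[predictor]]
    grid <- seq_along(lv) - 1
  } else {
    v <- ref_data[[predictor]]
    grid <- seq(min(v), max(v), length.out = grid_size)
  }
  yhat <- vapply(grid, function(g) {
    Xg <- d$X
    Xg[, j] <- g
    mean(predict_trees_cpp(object$trees, Xg, d$cat_levels,
                           object$params$learning_rate)$pred)
  }, 0) + object$f0
  out <- data.frame(value = if (is_cat) object$design$levels[[predictor]]
                            else grid,
                    yhat = yhat)
  if (!is_cat) {
    q <- quantile(ref_data[[predictor]], c(0.05, 0.95), type = 7)
    attr(out, "q5") <- unname(q[1])
    attr(out, "q95") <- unname(q[2])
  }
  out
}

#' Stepwise cross-validated selection of the number of trees
#'
#' Re-implementation of the stepwise BRT protocol: trees are added
#' `step_size` at a time to `cv_folds` fold models; the pooled out-of-fold
#' squared-error deviance is recorded at each step; stepping stops once the
#' minimum has not improved for `patience` steps (or `max_trees` is
#' reached, with a warning advising a smaller learning rate). The selected
#' tree count minimizes the CV deviance; a final model with that many trees
#' is then fitted on all rows.
#'
#' Fit statistics are computed at the selected size from the pooled
#' out-of-fold predictions: `cv_correlation` is their Pearson correlation
#' with the observed response, and `pct_deviance_explained` is
#' `100 * (1 - CV deviance / null deviance about the mean)`.
#'
#' @inheritParams brt.default
#' @param x predictor data.frame or formula (with `data`).
#' @param data data.frame when `x` is a formula.
#' @return a `brt` object with additional fields `n_trees_selected`,
#'   `cv_trace` (per-step CV deviance), `cv_correlation`,
#'   `pct_deviance_explained`, `oof_pred`, `cv_folds_assign`.
#' @export
brt_step <- function(x, y = NULL, params = brt_params(), data = NULL, ...) {
  if (inherits(x, "formula")) {
    tm <- stats::terms(x, data = data)
    predictors <- attr(tm, "term.labels")
    y <- data[[all.vars(x)[1]]]
    x <- data[predictors]
  }
  stopifnot(inherits(params, "brt_params"))
  n <- nrow(x)
  if (n < 2 * params$cv_folds) stop("too few rows for ", params$cv_folds,
                                    "-fold cross validation")
  if (anyNA(y)) stop("missing values in response")
  if (var(y) == 0) stop("constant response")
  if (!is.null(params$seed)) set.seed(params$seed)

  d <- build_design(x, names(x))
  K <- params$cv_folds
  folds <- sample(rep(seq_len(K), length.out = n))
  if (min(table(folds)) < 2) stop("a CV fold has fewer than 2 rows")

  Xtr <- Xte <- vector("list", K)
  pred_tr <- vector("list", K)
  f0k <- numeric(K)
  trees_k <- vector("list", K)
  oof <- numeric(n)
  for (k in seq_len(K)) {
    tr <- folds != k
    Xtr[[k]] <- d$X[tr, , drop = FALSE]
    Xte[[k]] <- d$X[!tr, , drop = FALSE]
    f0k[k] <- mean(y[tr])
    pred_tr[[k]] <- rep(f0k[k], sum(tr))
    oof[!tr] <- f0k[k]
    trees_k[[k]] <- list()
  }

  max_steps <- ceiling(params$max_trees / params$step_size)
  cv_dev <- numeric(0)
  oof_hist <- list()
  s <- 0
  repeat {
    s <- s + 1
    for (k in seq_len(K)) {
      r <- boost_more_cpp(Xtr[[k]], d$cat_levels, y[folds != k],
                          pred_tr[[k]], params$step_size,
                          params$tree_complexity, params$learning_rate,
                          params$bag_fraction, params$min_obs)
      pred_tr[[k]] <- r$pred
      oof[folds == k] <- oof[folds == k] +
        predict_trees_cpp(r$trees, Xte[[k]], d$cat_levels,
                          params$learning_rate)$pred
    }
    cv_dev[s] <- mean((y - oof)^2)
    oof_hist[[s]] <- oof
    best <- which.min(cv_dev)
    if (s - best >= params$patience) break
    if (s >= max_steps) {
      if (best == s)
        warning("CV minimum at max_trees; consider a smaller learning_rate")
      break
    }
  }
  best <- which.min(cv_dev)
  n_sel <- best * params$step_size
  oof_best <- oof_hist[[best]]
  null_dev <- mean((y - mean(y))^2)
  cv_cor <- cor(oof_best, y)
  pct_dev <- 100 * (1 - cv_dev[best] / null_dev)

  f0 <- mean(y)
  r <- boost_more_cpp(d$X, d$cat_levels, y, rep(f0, n), as.integer(n_sel),
                      params$tree_complexity, params$learning_rate,
                      params$bag_fraction, params$min_obs)
  fit <- new_brt(r$trees, f0, r$pred, r$influence, d, params, y)
  fit$n_trees_selected <- n_sel
  fit$cv_trace <- data.frame(step = seq_along(cv_dev),
                             n_trees = seq_along(cv_dev) * params$step_size,
                             cv_deviance = cv_dev)
  fit$cv_correlation <- cv_cor
  fit$pct_deviance_explained <- pct_dev
  fit$oof_pred <- oof_best
  fit$cv_folds_assign <- folds
  fit
}

#' Cross-validation fit statistics
#'
#' @param object a `brt` fit produced by [brt_step()].
#' @return list with `cv_correlation` and `pct_deviance_explained`.
#' @export
cv_statistics <- function(object) {
  if (is.null(object$cv_correlation))
    stop("fit has no CV statistics; use brt_step()")
  list(cv_correlation = object$cv_correlation,
       pct_deviance_explained = object$pct_deviance_explained)
}

#' @export
print.brt <- function(x, ...) {
  cat("Boosted regression trees (squared-error loss)\n")
  cat(sprintf("  trees: %d  tree complexity: %d  learning rate: %g  bag fraction: %g\n",
              x$n_trees, x$params$tree_complexity,
              x$params$learning_rate, x$params$bag_fraction))
  if (!is.null(x$n_trees_selected))
    cat(sprintf("  CV-selected trees: %d  cv correlation: %.3f  deviance explained: %.1f%%\n",
                x$n_trees_selected, x$cv_correlation,
                x$pct_deviance_explained))
  ri <- relative_influence(x)
  cat("  top influences:",
      paste(sprintf("%s %.1f%%", names(ri)[seq_len(min(3, length(ri)))],
                    ri[seq_len(min(3, length(ri)))]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Summarize a BRT fit
#'
#' @param object a `brt` fit.
#' @param plotit draw a barplot of relative influence.
#' @param ... unused.
#' @return data.frame of predictors and relative influence (invisible if
#'   plotted).
#' @export
summary.brt <- function(object, plotit = FALSE, ...) {
  ri <- relative_influence(object)
  out <- data.frame(predictor = names(ri), relative_influence = unname(ri))
  if (plotit) {
    op <- par(mar = c(4, 7, 1, 1)); on.exit(par(op))
    barplot(rev(ri), horiz = TRUE, las = 1,
            xlab = "relative influence (%)")
  }
  out
}

#' @export
residuals.brt <- function(object, ...) object$y - object$fitted

#' Plot a partial-dependence curve
#'
#' @param x a `brt` fit.
#' @param predictor predictor to plot (default: highest influence).
#' @param ref_data reference data for the dependence average (required).
#' @param ... passed to [graphics::plot()].
#' @export
plot.brt <- function(x, predictor = NULL, ref_data, ...) {
  if (is.null(predictor))
    predictor <- names(relative_influence(x))[1]
  pd <- partial_dependence(x, predictor, ref_data)
  if (is.numeric(pd$value)) {
    plot(pd$value, pd$yhat, type = "l", xlab = predictor,
         ylab = "marginal S'", ...)
    q5 <- attr(pd, "q5"); q95 <- attr(pd, "q95")
    graphics::abline(v = c(q5, q95), lty = 2, col = "grey40")
    rug(ref_data[[predictor]])
  } else {
    barplot(pd$yhat, names.arg = pd$value, xlab = predictor,
            ylab = "marginal S'", ...)
  }
  invisible(pd)
}
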