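#' Bootstrapped BRT ensemble
#'
#' Runs `n_runs` independent [brt_step()] fits, each on a random sample of
#' `sample_size` rows drawn without replacement with a run-specific seed,
#' and averages the results: median and interquartile range of relative
#' influence per predictor, of the CV fit statistics, and grid-aligned mean
#' partial-dependence curves (the common grid is fixed from the full
#' table's predictor quantiles so curves are comparable across runs).
#'
#' @param data data.frame with the response and predictors.
#' @param response response column name.
#' @param predictors predictor column names.
#' @param params a [brt_params()] (its `seed` field is ignored; per-run
#'   seeds are derived from `seed`).
#' @param n_runs number of bootstrap runs (default 20).
#' @param sample_size rows sampled per run (default 10000; lowered with a
#'   warning when the table is smaller).
#' @param seed base seed; run r uses `seed + r`.
#' @param grid_size points per partial-dependence grid (default 50).
#' @param pd_ref_cap reference rows per partial-dependence average.
#' @param compute_pd compute the averaged partial-dependence curves
#'   (default `TRUE`; skipping them speeds up influence-only ensembles,
#'   e.g. the preliminary pruning pass).
#' @return object of class `brt_ensemble`: `influence` (runs x predictors
#'   matrix), `influence_summary`, `cv_stats` (per run),
#'   `cv_summary`, `pd` (per predictor: grid with mean and IQR across
#'   runs), `n_trees_selected`, `failed_runs`.
#' @export
brt_ensemble <- function(data, response, predictors,
                         params = brt_params(), n_runs = 20,
                         sample_size = 10000, seed = 1L,
                         grid_size = 50, pd_ref_cap = 500,
                         compute_pd = TRUE) {
  stopifnot(n_runs >= 1)
  if (!response %in% names(data)) stop("response column not found")
  miss <- setdiff(predictors, names(data))
  if (length(miss)) stop("predictors not found: ",
                         paste(miss, collapse = ", "))
  n <- nrow(data)
  if (sample_size > n) {
    warning("sample_size lowered to table size (", n, ")")
    sample_size <- n
  }

  grids <- lapply(predictors, function(p) {
    v <- data[[p]]
    if (is.numeric(v)) seq(min(v), max(v), length.out = grid_size)
    else sort(unique(as.character(v)))
  })
  names(grids) <- predictors

  inf_mat <- matrix(NA_real_, n_runs, length(predictors),
                    dimnames = list(NULL, predictors))
  cv_stats <- data.frame(run = seq_len(n_runs), cv_correlation = NA_real_,
                         pct_deviance_explained = NA_real_,
                         n_trees = NA_integer_)
  pd_runs <- lapply(predictors, function(p)
    matrix(NA_real_, n_runs, length(grids[[p]])))
  names(pd_runs) <- predictors
  failed <- integer(0)

  for (r in seq_len(n_runs)) {
    run_params <- params
    run_params$seed <- as.integer(seed) + r
    res <- tryCatch({
      set.seed(run_params$seed)
      rows <- sample(n, sample_size)
      dsub <- data[rows, , drop = FALSE]
      fit <- brt_step(dsub[predictors], dsub[[response]], run_params)
      inf <- relative_influence(fit)
      inf_mat[r, names(inf)] <- inf
      cv_stats$cv_correlation[r] <- fit$cv_correlation
      cv_stats$pct_deviance_explained[r] <- fit$pct_deviance_explained
      cv_stats$n_trees[r] <- fit$n_trees_selected
      if (compute_pd) {
        d <- build_design(dsub[predictors], predictors,
                          levels = fit$design$levels)
        keep <- unique(round(seq(1, nrow(d$X), length.out = pd_ref_cap)))
        Xr <- d$X[keep, , drop = FALSE]
        for (p in predictors) {
          j <- match(p, predictors)
          gv <- grids[[p]]
          gnum <- if (d$cat_levels[j] > 0)
            match(gv, fit$design$levels[[p]]) - 1 else gv
          pd_runs[[p]][r, ] <- vapply(gnum, function(g) {
            Xg <- Xr; Xg[, j] <- g
            mean(predict_trees_cpp(fit$trees, Xg, d$cat_levels,
                                   run_params$learning_rate)$pred)
          }, 0) + fit$f0
        }
      }
      TRUE
    }, error = function(e) {
      message("ensemble run ", r, " failed: ", conditionMessage(e))
      FALSE
    })
    if (!isTRUE(res)) failed <- c(failed, r)
  }
  if (length(failed) > n_runs / 2)
    stop("more than half of the ensemble runs failed")

  ok <- setdiff(seq_len(n_runs), failed)
  qs <- function(v) c(median = median(v), q25 = unname(quantile(v, 0.25)),
                      q75 = unname(quantile(v, 0.75)))
  infs <- t(apply(inf_mat[ok, , drop = FALSE], 2, qs))
  influence_summary <- data.frame(predictor = rownames(infs),
                                  median = infs[, 1], q25 = infs[, 2],
                                  q75 = infs[, 3], row.names = NULL)
  influence_summary <- influence_summary[
    order(-influence_summary$median), ]

  pd <- if (!compute_pd) NULL else lapply(predictors, function(p) {
    m <- pd_runs[[p]][ok, , drop = FALSE]
    v <- data[[p]]
    out <- data.frame(value = grids[[p]],
                      mean = colMeans(m),
                      q25 = apply(m, 2, quantile, 0.25),
                      q75 = apply(m, 2, quantile, 0.75))
    if (is.numeric(v)) {
      attr(out, "q5") <- unname(quantile(v, 0.05, type = 7))
      attr(out, "q95") <- unname(quantile(v, 0.95, type = 7))
    }
    out
  })
  if (!is.null(pd)) names(pd) <- predictors

  structure(list(influence = inf_mat[ok, , drop = FALSE],
                 influence_summary = influence_summary,
                 cv_stats = cv_stats[ok, ],
                 cv_summary = list(
                   cv_correlation = qs(cv_stats$cv_correlation[ok]),
                   pct_deviance_explained =
                     qs(cv_stats$pct_deviance_explained[ok])),
                 pd = pd, predictors = predictors, response = response,
                 n_runs = n_runs, sample_size = sample_size,
                 failed_runs = failed, params = params, seed = seed),
            class = "brt_ensemble")
}

#' @export
print.brt_ensemble <- function(x, ...) {
  cat(sprintf("BRT ensemble: %d runs of %d rows, response '%s'\n",
              x$n_runs - length(x$failed_runs), x$sample_size, x$response))
  cat(sprintf("  cv correlation (median [IQR]): %.3f [%.3f, %.3f]\n",
              x$cv_summary$cv_correlation["median"],
              x$cv_summary$cv_correlation["q25"],
              x$cv_summary$cv_correlation["q75"]))
  cat(sprintf("  deviance explained (median [IQR]): %.1f%% [%.1f, %.1f]\n",
              x$cv_summary$pct_deviance_explained["median"],
              x$cv_summary$pct_deviance_explained["q25"],
              x$cv_summary$pct_deviance_explained["q75"]))
  cat("  relative influence (median %):\n")
  s <- x$influence_summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-12s %6.2f\n", s$predictor[i], s$median[i]))
  invisible(x)
}

#' @rdname relative_influence
#' @export
relative_influence.brt_ensemble <- function(object, ...) {
  s <- object$influence_summary
  out <- s$median
  names(out) <- s$predictor
  out
}

#' Prune low-influence predictors
#'
#' Drops predictors whose median relative influence across the ensemble is
#' below `threshold_pct` (default 5%), the parsimony step applied after a
#' preliminary all-predictor ensemble.
#'
#' @param ensemble a [brt_ensemble()] result.
#' @param threshold_pct influence threshold in percent.
#' @return list with `keep`, `drop`, and the `influence` medians used.
#' @export
prune_predictors <- function(ensemble, threshold_pct = 5) {
  stopifnot(inherits(ensemble, "brt_ensemble"))
  med <- relative_influence(ensemble)
  drop <- names(med)[med < threshold_pct]
  keep <- names(med)[med >= threshold_pct]
  if (!length(keep)) stop("all predictors fall below the influence threshold")
  list(keep = keep, drop = drop, influence = med)
}
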