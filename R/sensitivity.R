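#' Configuration for the drought-sensitivity statistic
#'
#' @param timescales SPEI timescales (months) over which per-timescale
#'   sensitivities are computed and then maximized.
#' @param min_baseline_years minimum number of baseline-class years for a
#'   pixel's baseline EVI to be considered valid (default 3).
#' @param min_drought_years minimum number of drought-class years for a
#'   per-timescale sensitivity to be computed (default 1; a 17-year record
#'   makes stricter minima too lossy).
#' @param stat central tendency used for both baseline and drought-year
#'   EVI: `"mean"` (default) or `"median"`.
#' @param shared_baseline if `TRUE`, use a single baseline-year set (years
#'   classified baseline at every timescale) instead of each timescale's
#'   own baseline (the default).
#' @return list of class `sensitivity_config`.
#' @export
sensitivity_config <- function(timescales = c(3, 6, 12),
                               min_baseline_years = 3,
                               min_drought_years = 1,
                               stat = c("mean", "median"),
                               shared_baseline = FALSE) {
  stat <- match.arg(stat)
  structure(list(timescales = as.integer(timescales),
                 min_baseline_years = as.integer(min_baseline_years),
                 min_drought_years = as.integer(min_drought_years),
                 stat = stat, shared_baseline = shared_baseline),
            class = "sensitivity_config")
}

# central-tendency helper over groups; returns list(value, n) aligned to pids
group_stat <- function(values, group, pids, stat) {
  f <- factor(group, levels = pids)
  n <- as.integer(table(f))
  v <- if (stat == "median") tapply(values, f, median)
       else tapply(values, f, mean)
  list(value = as.numeric(v), n = n)
}

# join EVI rows to drought classes for one timescale
evi_with_class <- function(evi, spei_table, timescale) {
  st <- spei_table[spei_table$timescale == timescale, , drop = FALSE]
  if (!nrow(st)) stop("spei_table has no rows at timescale ", timescale)
  idx <- match(paste(evi$pixel_id, evi$year), paste(st$pixel_id, st$year))
  if (all(is.na(idx))) stop("EVI and SPEI tables share no pixel-years")
  data.frame(pixel_id = evi$pixel_id, year = evi$year,
             evi_summer = evi$evi_summer,
             drought_class = st$drought_class[idx])[!is.na(idx), ]
}

#' Baseline EVI per pixel for one SPEI timescale
#'
#' The baseline EVI is the central tendency of summer EVI over years
#' classified as baseline (-1 < SPEI < 1) at the given timescale. Pixels
#' with fewer than `min_baseline_years` baseline years are flagged invalid.
#'
#' @param evi EVI table (`pixel_id`, `year`, `evi_summer`).
#' @param spei_table SPEI table from [compute_spei()].
#' @param timescale months.
#' @param min_baseline_years minimum baseline-year count (default 3).
#' @param stat `"mean"` or `"median"`.
#' @return data.frame `pixel_id`, `baseline_evi`, `n_baseline_years`,
#'   `valid`.
#' @export
baseline_evi <- function(evi, spei_table, timescale,
                         min_baseline_years = 3, stat = "mean") {
  ec <- evi_with_class(evi, spei_table, timescale)
  pids <- unique(evi$pixel_id)
  b <- ec[ec$drought_class == "baseline", , drop = FALSE]
  g <- group_stat(b$evi_summer, b$pixel_id, pids, stat)
  data.frame(pixel_id = pids, baseline_evi = g$value,
             n_baseline_years = g$n,
             valid = g$n >= min_baseline_years & !is.na(g$value) &
               g$value > 0)
}

#' Per-timescale drought sensitivity S'
#'
#' `S' = 100 * (baseline_EVI - mean EVI over drought years) / baseline_EVI`
#' for years of the requested drought class at the given timescale: the
#' percent decrease in EVI under drought relative to baseline conditions.
#' Negative values (greening under drought) are retained.
#'
#' @inheritParams baseline_evi
#' @param class `"moderate"` or `"severe"`.
#' @param min_drought_years minimum drought-year count (default 1).
#' @return data.frame `pixel_id`, `s` (percent), `n_years`, `valid`.
#' @export
timescale_sensitivity <- function(evi, spei_table, timescale,
                                  class = c("moderate", "severe"),
                                  min_baseline_years = 3,
                                  min_drought_years = 1, stat = "mean") {
  class <- match.arg(class)
  base <- baseline_evi(evi, spei_table, timescale, min_baseline_years, stat)
  ec <- evi_with_class(evi, spei_table, timescale)
  d <- ec[ec$drought_class == class, , drop = FALSE]
  g <- group_stat(d$evi_summer, d$pixel_id, base$pixel_id, stat)
  valid <- base$valid & g$n >= min_drought_years & !is.na(g$value)
  s <- ifelse(valid, 100 * (base$baseline_evi - g$value) / base$baseline_evi,
              NA_real_)
  data.frame(pixel_id = base$pixel_id, s = s, n_years = g$n, valid = valid)
}

#' Maximum sensitivity across timescales
#'
#' @param x named numeric vector of per-timescale sensitivities (names are
#'   timescales in months); invalid entries as `NA`.
#' @return list with `s_max`, `timescale` (months attaining it), `valid`.
#' @export
max_sensitivity <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(list(s_max = NA_real_, timescale = NA_integer_,
                            valid = FALSE))
  i <- which.max(replace(x, !ok, -Inf))
  list(s_max = unname(x[i]), timescale = as.integer(names(x)[i]),
       valid = TRUE)
}

#' Full drought-sensitivity table
#'
#' Computes baseline EVI and moderate/severe sensitivity per timescale,
#' maximizes across timescales, and records validity flags, year counts,
#' and an exclusion summary (attribute `"exclusions"`).
#'
#' @param evi EVI table.
#' @param spei_table SPEI table from [compute_spei()].
#' @param config a [sensitivity_config()].
#' @return data.frame with one row per pixel: per-timescale columns
#'   (`baseline_<k>`, `s_mod_<k>`, `s_sev_<k>`, `n_base_<k>`, `n_mod_<k>`,
#'   `n_sev_<k>`), the maxima `s_mod_max`, `s_sev_max` with the attaining
#'   `timescale_mod`, `timescale_sev`, and `valid_mod`, `valid_sev`.
#' @export
sensitivity_table <- function(evi, spei_table,
                              config = sensitivity_config()) {
  stopifnot(inherits(config, "sensitivity_config"))
  need <- c("pixel_id", "year", "evi_summer")
  miss <- setdiff(need, names(evi))
  if (length(miss)) stop("EVI table missing columns: ",
                         paste(miss, collapse = ", "))
  pids <- unique(evi$pixel_id)
  res <- data.frame(pixel_id = pids)
  smod <- ssev <- matrix(NA_real_, length(pids), length(config$timescales),
                         dimnames = list(NULL, config$timescales))

  shared_ok <- NULL
  if (config$shared_baseline) {
    # years baseline at every configured timescale
    cls_all <- lapply(config$timescales, function(ts)
      evi_with_class(evi, spei_table, ts))
    ok <- Reduce(`&`, lapply(cls_all, function(d)
      d$drought_class == "baseline"))
    shared_ok <- ok
  }

  for (k in seq_along(config$timescales)) {
    ts <- config$timescales[k]
    if (config$shared_baseline) {
      ec <- evi_with_class(evi, spei_table, ts)
      b <- ec[shared_ok, , drop = FALSE]
      g <- group_stat(b$evi_summer, b$pixel_id, pids, config$stat)
      base <- data.frame(pixel_id = pids, baseline_evi = g$value,
                         n_baseline_years = g$n,
                         valid = g$n >= config$min_baseline_years &
                           !is.na(g$value) & g$value > 0)
    } else {
      base <- baseline_evi(evi, spei_table, ts,
                           config$min_baseline_years, config$stat)
    }
    ec <- evi_with_class(evi, spei_table, ts)
    for (cls in c("moderate", "severe")) {
      d <- ec[ec$drought_class == cls, , drop = FALSE]
      g <- group_stat(d$evi_summer, d$pixel_id, pids, config$stat)
      valid <- base$valid & g$n >= config$min_drought_years & !is.na(g$value)
      s <- ifelse(valid,
                  100 * (base$baseline_evi - g$value) / base$baseline_evi,
                  NA_real_)
      if (cls == "moderate") {
        smod[, k] <- s
        res[[paste0("s_mod_", ts)]] <- s
        res[[paste0("n_mod_", ts)]] <- g$n
      } else {
        ssev[, k] <- s
        res[[paste0("s_sev_", ts)]] <- s
        res[[paste0("n_sev_", ts)]] <- g$n
      }
    }
    res[[paste0("baseline_", ts)]] <- base$baseline_evi
    res[[paste0("n_base_", ts)]] <- base$n_baseline_years
  }

  pick <- function(m) {
    apply(m, 1, function(v) {
      r <- max_sensitivity(v)
      c(r$s_max, if (is.na(r$timescale)) NA_real_ else r$timescale)
    })
  }
  pm <- pick(smod); ps <- pick(ssev)
  res$s_mod_max <- pm[1, ]; res$timescale_mod <- as.integer(pm[2, ])
  res$s_sev_max <- ps[1, ]; res$timescale_sev <- as.integer(ps[2, ])
  res$valid_mod <- !is.na(res$s_mod_max)
  res$valid_sev <- !is.na(res$s_sev_max)

  attr(res, "exclusions") <- c(
    n_pixels = length(pids),
    invalid_mod = sum(!res$valid_mod),
    invalid_sev = sum(!res$valid_sev))
  res
}
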