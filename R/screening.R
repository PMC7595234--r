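#' Mann-Kendall trend test with Sen slope
#'
#' Nonparametric trend test for short annual series:
#' `S = sum_{i<j} sign(x_j - x_i)`, variance with tie correction
#' `Var(S) = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` (sum over tie
#' groups), Z with the +/-1 continuity correction, two-sided p-value from
#' the standard normal, and Sen slope = median of all pairwise slopes.
#'
#' @param x annual values in time order (>= 8 years).
#' @param alpha significance level for the trend flag (default 0.05).
#' @return list with `S`, `var_S`, `Z`, `p_value`, `sen_slope`,
#'   `trend_flag`.
#' @export
mann_kendall <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 8) stop("Mann-Kendall test needs at least 8 years, got ", n)
  if (any(!is.finite(x))) stop("non-finite values in series")
  d <- outer(x, x, "-")            # d[i, j] = x_i - x_j
  up <- upper.tri(d)               # pairs i < j give x_j - x_i = -d[i,j]
  S <- sum(sign(-d[up]))
  ties <- table(x)
  tt <- ties[ties > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(tt * (tt - 1) * (2 * tt + 5))) / 18
  Z <- if (S > 0) (S - 1) / sqrt(var_S)
       else if (S < 0) (S + 1) / sqrt(var_S)
       else 0
  p <- 2 * pnorm(-abs(Z))
  dt <- outer(seq_len(n), seq_len(n), "-")
  sen <- median((-d[up]) / (-dt[up]))
  list(S = S, var_S = var_S, Z = Z, p_value = p, sen_slope = sen,
       trend_flag = p < alpha)
}

#' Flag pixels with long-term EVI trends
#'
#' Applies [mann_kendall()] per pixel to the annual summer-EVI series.
#'
#' @param evi EVI table (`pixel_id`, `year`, `evi_summer`).
#' @param alpha significance level (default 0.05).
#' @return data.frame `pixel_id`, `sen_slope`, `p_value`, `trend_flag`.
#' @export
trend_screen <- function(evi, alpha = 0.05) {
  evi <- evi[order(evi$pixel_id, evi$year), ]
  pids <- unique(evi$pixel_id)
  g <- factor(evi$pixel_id, levels = pids)
  res <- lapply(split(evi$evi_summer, g), mann_kendall, alpha = alpha)
  data.frame(pixel_id = pids,
             sen_slope = vapply(res, `[[`, 0, "sen_slope"),
             p_value = vapply(res, `[[`, 0, "p_value"),
             trend_flag = vapply(res, `[[`, TRUE, "trend_flag"),
             row.names = NULL)
}

#' Apply disturbance, trend, and landcover exclusions
#'
#' Retained pixels are those that are not disturbed, show no long-term
#' trend, and carry a modeled landcover. Exclusions are attributed to the
#' first matching rule in the order disturbed > trending > landcover, and
#' a ledger of counts per rule is returned.
#'
#' @param pixels pixel table with a `pixel_id` column (and `ecosystem` if
#'   `keep_landcover` is given).
#' @param disturbed_flag logical vector aligned to `pixels` rows.
#' @param trend_flag logical vector aligned to `pixels` rows.
#' @param keep_landcover optional character vector of modeled ecosystem
#'   codes; pixels outside it are excluded.
#' @return list with `retained` (subset of `pixels`) and `ledger` (named
#'   counts: `disturbed`, `trending`, `landcover`, `retained`, `total`).
#' @export
apply_exclusions <- function(pixels, disturbed_flag, trend_flag,
                             keep_landcover = NULL) {
  n <- nrow(pixels)
  if (length(disturbed_flag) != n || length(trend_flag) != n)
    stop("disturbance mask and trend flags must cover all pixels")
  if (anyNA(disturbed_flag) || anyNA(trend_flag))
    stop("missing mask entries")
  lc_bad <- if (is.null(keep_landcover)) rep(FALSE, n)
            else !(pixels$ecosystem %in% keep_landcover)
  rule <- ifelse(disturbed_flag, "disturbed",
          ifelse(trend_flag, "trending",
          ifelse(lc_bad, "landcover", "retained")))
  ledger <- c(disturbed = sum(rule == "disturbed"),
              trending = sum(rule == "trending"),
              landcover = sum(rule == "landcover"),
              retained = sum(rule == "retained"),
              total = n)
  list(retained = pixels[rule == "retained", , drop = FALSE],
       ledger = ledger)
}

#' Cumulative drought exposure per pixel
#'
#' 100 times the fraction of years in `period` whose SPEI at
#' `timescale` is at or below `threshold`.
#'
#' @param spei_table SPEI table from [compute_spei()].
#' @param period years over which exposure is evaluated (default
#'   1990:2016).
#' @param timescale SPEI timescale in months (default 12).
#' @param threshold SPEI cutoff (default -1, i.e. any drought).
#' @return data.frame `pixel_id`, `drought_exp` (percent).
#' @export
drought_exposure <- function(spei_table, period = 1990:2016,
                             timescale = 12, threshold = -1) {
  st <- spei_table[spei_table$timescale == timescale, , drop = FALSE]
  if (!nrow(st)) stop("spei_table has no rows at timescale ", timescale)
  covered <- unique(st$year)
  if (!all(period %in% covered))
    stop("SPEI table does not cover the exposure period ",
         min(period), "-", max(period))
  st <- st[st$year %in% period, ]
  pids <- unique(st$pixel_id)
  g <- factor(st$pixel_id, levels = pids)
  frac <- tapply(st$spei <= threshold, g, mean)
  data.frame(pixel_id = pids, drought_exp = 100 * as.numeric(frac))
}
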