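#' Configuration for multi-timescale SPEI computation
#'
#' @param timescales aggregation windows in months (default 3, 6, 12:
#'   summer, winter-through-summer, and the entire previous year).
#' @param end_month calendar month anchoring each annual value (default 8,
#'   August, so the 3-month window covers the June-August EVI season).
#' @param calibration_years year range (vector) used to fit the
#'   standardization; `NULL` (default) calibrates on the full record.
#' @param method `"log-logistic"` (3-parameter log-logistic fitted by
#'   unbiased probability-weighted moments, the conventional SPEI
#'   distribution) or `"empirical"` (Gringorten plotting positions).
#' @param baseline_low,baseline_high,severe_max drought-class thresholds:
#'   severe is `spei <= severe_max`, moderate `severe_max < spei <=
#'   baseline_low`, baseline `baseline_low < spei < baseline_high`, pluvial
#'   `spei >= baseline_high`.
#' @return list of class `spei_config`.
#' @export
spei_config <- function(timescales = c(3, 6, 12), end_month = 8,
                        calibration_years = NULL,
                        method = c("log-logistic", "empirical"),
                        baseline_low = -1, baseline_high = 1,
                        severe_max = -1.5) {
  method <- match.arg(method)
  stopifnot(all(timescales >= 1), all(timescales <= 48),
            end_month %in% 1:12,
            baseline_low < baseline_high, severe_max < baseline_low)
  structure(list(timescales = as.integer(timescales),
                 end_month = as.integer(end_month),
                 calibration_years = calibration_years, method = method,
                 baseline_low = baseline_low, baseline_high = baseline_high,
                 severe_max = severe_max),
            class = "spei_config")
}

#' Monthly climatic water balance
#'
#' D = precipitation - potential evapotranspiration, per pixel-month.
#' Validates that every pixel has a complete, gap-free monthly record.
#'
#' @param climate data.frame with columns `pixel_id`, `year`, `month`,
#'   `prcp`, `pet`.
#' @return data.frame `pixel_id`, `year`, `month`, `d` (mm), ordered by
#'   pixel, year, month.
#' @export
water_balance <- function(climate) {
  need <- c("pixel_id", "year", "month", "prcp", "pet")
  miss <- setdiff(need, names(climate))
  if (length(miss)) stop("climate table missing columns: ",
                         paste(miss, collapse = ", "))
  cl <- climate[order(climate$pixel_id, climate$year, climate$month), ]
  # gap check: within each pixel, consecutive month indices
  midx <- cl$year * 12L + cl$month
  new_pix <- c(TRUE, cl$pixel_id[-1] != cl$pixel_id[-nrow(cl)])
  gaps <- !new_pix & diff(c(midx[1], midx)) != 1
  if (any(gaps)) {
    bad <- unique(cl$pixel_id[gaps])
    stop("gaps in monthly record for pixel(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  data.frame(pixel_id = cl$pixel_id, year = cl$year, month = cl$month,
             d = cl$prcp - cl$pet)
}

# reshape a complete balance table to a months x pixels matrix; all pixels
# must share the same (year, month) sequence
balance_matrix <- function(wb) {
  pid <- unique(wb$pixel_id)
  np <- length(pid)
  nm <- nrow(wb) / np
  if (nm != floor(nm))
    stop("pixels have differing record lengths")
  nm <- as.integer(nm)
  yr <- wb$year[seq_len(nm)]
  mo <- wb$month[seq_len(nm)]
  if (!all(wb$year == rep(yr, np)) || !all(wb$month == rep(mo, np)))
    stop("pixels have differing year/month coverage")
  list(mat = matrix(wb$d, nrow = nm, ncol = np), pixel_id = pid,
       year = yr, month = mo)
}

#' Aggregate the water balance over a timescale
#'
#' The value for year y is the sum of D over the `timescale` months ending
#' at `end_month` of year y. Years without enough antecedent history are
#' omitted with a warning.
#'
#' @param wb water-balance table from [water_balance()].
#' @param timescale window length in months.
#' @param end_month anchoring month (default 8, August).
#' @return data.frame `pixel_id`, `year`, `balance` (mm).
#' @export
aggregate_balance <- function(wb, timescale, end_month = 8) {
  bm <- balance_matrix(wb)
  pos <- which(bm$month == end_month)
  ok <- pos >= timescale
  if (!any(ok))
    stop("no year has ", timescale, " months of history before month ",
         end_month)
  if (!all(ok))
    warning(sum(!ok), " year(s) omitted: fewer than ", timescale,
            " months of antecedent record")
  pos <- pos[ok]
  cs <- apply(bm$mat, 2, cumsum)
  cs <- rbind(0, cs)
  val <- cs[pos + 1, , drop = FALSE] - cs[pos + 1 - timescale, , drop = FALSE]
  data.frame(pixel_id = rep(bm$pixel_id, each = length(pos)),
             year = rep(bm$year[pos], length(bm$pixel_id)),
             balance = as.numeric(val))
}

# unbiased probability-weighted moments w_s = E[X (1-F)^s], s = 0, 1, 2,
# estimated with the exact combinatorial weights C(n-i, s)/C(n-1, s)
pwm_unbiased <- function(x) {
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  w0 <- mean(x)
  w1 <- sum(x * (n - i)) / (n * (n - 1))
  w2 <- sum(x * (n - i) * (n - i - 1)) / (n * (n - 1) * (n - 2))
  c(b0 = w0, b1 = w1, b2 = w2)
}

# 3-parameter log-logistic fit by PWM; returns NULL when the moment
# equations have no admissible solution (shape must exceed 1 for the
# required gamma functions to exist)
fit_loglogistic <- function(x) {
  b <- pwm_unbiased(x)
  den <- 6 * b["b1"] - b["b0"] - 6 * b["b2"]
  if (!is.finite(den) || den == 0) return(NULL)
  beta <- (2 * b["b1"] - b["b0"]) / den
  if (!is.finite(beta) || beta <= 1.01) return(NULL)
  g12 <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
  alpha <- (b["b0"] - 2 * b["b1"]) * beta / g12
  if (!is.finite(alpha) || alpha <= 0) return(NULL)
  gam <- b["b0"] - alpha * g12
  list(alpha = unname(alpha), beta = unname(beta), gamma = unname(gam))
}

#' Standardize an aggregated water-balance series to SPEI
#'
#' The log-logistic method fits a 3-parameter log-logistic distribution by
#' unbiased probability-weighted moments over the calibration subset and
#' maps its CDF through the inverse standard normal; if the fit is
#' inadmissible it falls back to the empirical method with a warning. The
#' empirical method uses Gringorten plotting positions
#' `(r - 0.44)/(n + 0.12)` over the calibration subset (values outside the
#' calibration range are clamped to the extreme positions). Both are
#' strictly non-decreasing in the aggregated balance.
#'
#' @param x aggregated balance values (one pixel, one timescale).
#' @param calib indices of `x` forming the calibration period (default all).
#' @param method `"log-logistic"` or `"empirical"`.
#' @return numeric vector of SPEI values, same length as `x`.
#' @export
spei_standardize <- function(x, calib = seq_along(x),
                             method = c("log-logistic", "empirical")) {
  method <- match.arg(method)
  xc <- x[calib]
  if (length(xc) < 5) stop("calibration period too short (< 5 years)")
  if (var(xc) == 0) stop("degenerate (zero-variance) balance series")
  if (method == "log-logistic") {
    fit <- fit_loglogistic(xc)
    if (is.null(fit)) {
      warning("log-logistic fit failed; falling back to empirical method")
      return(spei_standardize(x, calib, "empirical"))
    }
    u <- pmax(x - fit$gamma, 1e-10)
    f <- 1 / (1 + (fit$alpha / u)^fit$beta)
    f <- pmin(pmax(f, 1e-7), 1 - 1e-7)
    qnorm(f)
  } else {
    n <- length(xc)
    xs <- sort(xc)
    pp <- (seq_len(n) - 0.44) / (n + 0.12)
    # map through the calibration empirical CDF, clamped at the extremes
    z <- approx(xs, qnorm(pp), xout = x, ties = mean, rule = 2)$y
    z
  }
}

#' Classify SPEI values into drought classes
#'
#' Severe drought is `spei <= severe_max` (default -1.5), moderate drought
#' `severe_max < spei <= baseline_low` (default -1), baseline
#' `baseline_low < spei < baseline_high`, and pluvial
#' `spei >= baseline_high` (default 1). The four classes partition the real
#' line; ties at thresholds go to the dry side.
#'
#' @param spei numeric vector of finite SPEI values.
#' @param baseline_low,baseline_high,severe_max class thresholds.
#' @return factor with levels `pluvial`, `baseline`, `moderate`, `severe`.
#' @export
classify_drought <- function(spei, baseline_low = -1, baseline_high = 1,
                             severe_max = -1.5) {
  if (any(!is.finite(spei))) stop("non-finite SPEI value")
  cls <- ifelse(spei <= severe_max, "severe",
         ifelse(spei <= baseline_low, "moderate",
         ifelse(spei < baseline_high, "baseline", "pluvial")))
  factor(cls, levels = c("pluvial", "baseline", "moderate", "severe"))
}

#' Compute the multi-timescale SPEI table
#'
#' Runs [water_balance()], [aggregate_balance()] and [spei_standardize()]
#' per pixel and timescale and attaches drought classes.
#'
#' @param climate monthly climate table (`pixel_id`, `year`, `month`,
#'   `prcp`, `pet`).
#' @param config a [spei_config()].
#' @return data.frame `pixel_id`, `year`, `timescale`, `spei`,
#'   `drought_class`.
#' @export
compute_spei <- function(climate, config = spei_config()) {
  stopifnot(inherits(config, "spei_config"))
  wb <- water_balance(climate)
  out <- vector("list", length(config$timescales))
  for (k in seq_along(config$timescales)) {
    ts <- config$timescales[k]
    ab <- aggregate_balance(wb, ts, config$end_month)
    pid <- unique(ab$pixel_id)
    yrs <- ab$year[ab$pixel_id == pid[1]]
    calib <- if (is.null(config$calibration_years)) seq_along(yrs)
             else which(yrs %in% config$calibration_years)
    if (length(calib) < 20)
      warning("calibration period has ", length(calib),
              " years; SPEI standardization is unstable below 20")
    m <- matrix(ab$balance, nrow = length(yrs))
    z <- apply(m, 2, spei_standardize, calib = calib,
               method = config$method)
    out[[k]] <- data.frame(pixel_id = rep(pid, each = length(yrs)),
                           year = rep(yrs, length(pid)),
                           timescale = ts,
                           spei = as.numeric(z))
  }
  res <- do.call(rbind, out)
  res$drought_class <- classify_drought(res$spei, config$baseline_low,
                                        config$baseline_high,
                                        config$severe_max)
  res
}
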