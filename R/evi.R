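#' Generate annual summer EVI series from the truth table and SPEI classes
#'
#' Each pixel-year's summer (June-August) mean EVI is its true baseline EVI
#' reduced multiplicatively according to the drought class of that year at
#' the pixel's true SPEI timescale:
#' `EVI = baseline * (1 - s) * exp(eps)`, `eps ~ N(0, noise_sd^2)`,
#' with `s = 0` in baseline and pluvial years, `s = s_mod_true` in moderate
#' drought years, and `s = s_sev_true` in severe drought years. Disturbed
#' pixels receive an abrupt permanent multiplicative drop at a uniformly
#' random year of the window; trending pixels an additive linear drift of
#' `trend_slope` EVI units per year.
#'
#' @param truth truth table from [simulate_truth()].
#' @param spei_table SPEI table from [compute_spei()] covering every pixel,
#'   the EVI years, and each pixel's `true_timescale`.
#' @param years EVI window years (default 2000:2016).
#' @param noise_sd lognormal noise sd (0 gives deterministic EVI).
#' @param disturbance_drop fractional permanent EVI loss at disturbance
#'   (default 0.4).
#' @param seed integer seed.
#' @return data.frame with columns `pixel_id`, `year`, `evi_summer`.
#' @export
simulate_evi <- function(truth, spei_table, years = 2000:2016,
                         noise_sd = 0.02, disturbance_drop = 0.4,
                         seed = 1L) {
  set.seed(seed)
  years <- sort(years)
  ny <- length(years); np <- nrow(truth)

  st <- spei_table[spei_table$year %in% years, , drop = FALSE]
  key_st <- paste(st$pixel_id, st$year, st$timescale)
  pid <- rep(truth$pixel_id, each = ny)
  yr <- rep(years, times = np)
  ts <- rep(truth$true_timescale, each = ny)
  idx <- match(paste(pid, yr, ts), key_st)
  if (anyNA(idx))
    stop("spei_table does not cover every pixel-year at the true timescale")
  cls <- st$drought_class[idx]

  s <- numeric(length(cls))
  s[cls == "moderate"] <- rep(truth$s_mod_true, each = ny)[cls == "moderate"]
  s[cls == "severe"] <- rep(truth$s_sev_true, each = ny)[cls == "severe"]

  evi <- rep(truth$baseline_evi_true, each = ny) * (1 - s)
  if (noise_sd > 0) evi <- evi * exp(rnorm(length(evi), sd = noise_sd))

  # disturbance: permanent step drop starting at a uniform-random year
  if (any(truth$disturbed_flag)) {
    dist_year <- years[1] + floor(runif(np) * ny)  # per pixel
    hit <- rep(truth$disturbed_flag, each = ny) & yr >= rep(dist_year, each = ny)
    evi[hit] <- evi[hit] * (1 - disturbance_drop)
  }
  # long-term linear trend
  if (any(truth$trend_flag)) {
    drift <- rep(truth$trend_slope, each = ny) * (yr - years[1])
    tr <- rep(truth$trend_flag, each = ny)
    evi[tr] <- evi[tr] + drift[tr]
  }
  evi <- pmin(evi, 0.99)

  data.frame(pixel_id = pid, year = yr, evi_summer = evi)
}
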