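#' Configuration for the synthetic landscape generator
#'
#' Defines the grid, the spatial-autocorrelation scale, the value ranges of
#' the landscape covariates, the rule assigning biomes and ecosystem types,
#' and the size of the 30-m-style subgrid carried by each 1-km pixel.
#'
#' Covariates are generated as spatially smoothed noise rescaled into
#' `covariate_ranges`, so each range is in the covariate's natural units:
#' elevation (m), actual evapotranspiration AET (mm), climatic water deficit
#' (mm), soil available water capacity (volumetric fraction), soil bulk
#' density (kg/m^3), water-table depth (m), compound topographic index CTI
#' (unitless), heat-load index HLI (unitless).
#'
#' The biome rule assigns shrub-steppe where the climatic water deficit
#' exceeds `deficit_threshold` (water-limited landscapes) and forest
#' elsewhere; within each biome, elevation terciles define three forest and
#' two shrub-steppe ecosystem types, so every pixel receives exactly one
#' biome and one ecosystem code.
#'
#' @param n_rows,n_cols grid dimensions in pixels.
#' @param smoothing_length moving-average half-width (pixels) used to
#'   spatially autocorrelate the covariate fields; 0 gives iid fields.
#' @param subgrid_size side length of the within-pixel subgrid used for the
#'   HLI / landcover / CTI aggregation (default 33, i.e. roughly 30-m cells
#'   in a 1-km pixel).
#' @param covariate_ranges named list of `c(min, max)` per covariate.
#' @param biome_rule list with `deficit_threshold` (mm).
#' @param seed integer seed; the generator is bit-reproducible under it.
#' @return an object of class `landscape_config`.
#' @export
landscape_config <- function(n_rows = 20, n_cols = 20, smoothing_length = 3,
                             subgrid_size = 33,
                             covariate_ranges = list(
                               elev    = c(50, 3000),
                               aet     = c(150, 800),
                               deficit = c(0, 800),
                               soil_awc = c(0.05, 0.35),
                               soil_bd = c(900, 1700),
                               wtd     = c(1, 60),
                               cti     = c(3, 15),
                               hli     = c(0.3, 1.05)
                             ),
                             biome_rule = list(deficit_threshold = 400),
                             seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, subgrid_size >= 1,
            smoothing_length >= 0)
  for (nm in names(covariate_ranges)) {
    r <- covariate_ranges[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] > r[2])
      stop("invalid range for covariate '", nm, "': need finite min <= max")
  }
  needed <- c("elev", "aet", "deficit", "soil_awc", "soil_bd", "wtd",
              "cti", "hli")
  missing <- setdiff(needed, names(covariate_ranges))
  if (length(missing))
    stop("covariate_ranges missing: ", paste(missing, collapse = ", "))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 smoothing_length = as.integer(smoothing_length),
                 subgrid_size = as.integer(subgrid_size),
                 covariate_ranges = covariate_ranges,
                 biome_rule = biome_rule, seed = as.integer(seed)),
            class = "landscape_config")
}

# moving-average smoothing of a white-noise grid; half-width L in pixels.
# Separable box filter with edge renormalisation, so the field keeps unit
# scale near the borders.
smooth_grid <- function(z, L) {
  if (L <= 0) return(z)
  k <- rep(1, 2 * L + 1)
  sm_dim <- function(m) {
    num <- apply(m, 2, function(col)
      as.numeric(stats::filter(col, k, sides = 2)))
    den <- apply(matrix(1, nrow(m), ncol(m)), 2, function(col)
      as.numeric(stats::filter(col, k, sides = 2)))
    num[is.na(num)] <- 0; den[is.na(den)] <- 1
    matrix(num / den, nrow(m), ncol(m))
  }
  z2 <- sm_dim(z)
  t(sm_dim(t(z2)))
}

rescale_range <- function(x, lo, hi) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep((lo + hi) / 2, length(x)))
  lo + (hi - lo) * (x - rng[1]) / (rng[2] - rng[1])
}

#' Generate a synthetic landscape of 1-km pixels
#'
#' Draws spatially autocorrelated covariate fields (smoothed white noise
#' rescaled into the configured ranges), assigns biome and ecosystem codes
#' by the configured rule, and attaches to each pixel a within-pixel subgrid
#' of HLI values, landcover codes, and CTI values. The subgrids are
#' aggregated with [aggregate_subgrid()] into the pixel-level shade density
#' (percent of subcells with HLI <= 0.6), majority landcover, and mean CTI.
#'
#' @param config a [landscape_config()].
#' @param subgrids logical; keep the raw subgrid arrays in the result
#'   (`$subgrids`)? Defaults to `FALSE` to save memory; the aggregated
#'   columns are always present.
#' @return a list with `pixels` (data.frame, one row per pixel: `pixel_id`,
#'   `row`, `col`, the eight covariates, `shade_dens`, `landcover`,
#'   `biome`, `ecosystem`) and, if requested, `subgrids` (list of 3D arrays
#'   `hli`, `landcover`, `cti` with dimensions pixel x sub x sub).
#' @export
simulate_landscape <- function(config, subgrids = FALSE) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols; n <- nr * nc
  L <- config$smoothing_length

  cov <- list()
  for (nm in names(config$covariate_ranges)) {
    z <- matrix(rnorm(n), nr, nc)
    z <- smooth_grid(z, L)
    r <- config$covariate_ranges[[nm]]
    cov[[nm]] <- rescale_range(as.numeric(z), r[1], r[2])
  }

  px <- data.frame(pixel_id = seq_len(n),
                   row = rep(seq_len(nr), times = nc),
                   col = rep(seq_len(nc), each = nr))
  for (nm in names(cov)) px[[nm]] <- cov[[nm]]

  # biome / ecosystem rule: deficit splits the biomes, elevation terciles
  # split ecosystems within biome
  steppe <- px$deficit > config$biome_rule$deficit_threshold
  px$biome <- ifelse(steppe, "shrub-steppe", "forest")
  eco <- character(n)
  if (any(!steppe)) {
    q <- quantile(px$elev[!steppe], c(1 / 3, 2 / 3), type = 7)
    eco[!steppe] <- c("wet_conifer", "mixed_conifer",
                      "subalpine")[1L + findInterval(px$elev[!steppe], q)]
  }
  if (any(steppe)) {
    q <- quantile(px$elev[steppe], 0.5, type = 7)
    eco[steppe] <- ifelse(px$elev[steppe] > q, "dwarf_sagebrush",
                          "tall_sagebrush")
  }
  px$ecosystem <- eco

  # within-pixel 30-m-style subgrids: HLI around the pixel HLI, landcover
  # mostly the pixel's own ecosystem with a sprinkling of a neighbour code,
  # CTI around the pixel mean
  s <- config$subgrid_size
  eco_codes <- sort(unique(px$ecosystem))
  hli_sub <- array(rnorm(n * s * s, sd = 0.12), c(n, s, s)) +
    array(rep(px$hli, s * s), c(n, s, s))
  lc_sub <- array(match(px$ecosystem, eco_codes), c(n, s, s))
  if (length(eco_codes) > 1 && s > 1) {
    mix <- array(runif(n * s * s) < 0.15, c(n, s, s))
    other <- sample(length(eco_codes), n, replace = TRUE)
    lc_sub[mix] <- array(rep(other, s * s), c(n, s, s))[mix]
  }
  cti_sub <- array(rnorm(n * s * s, sd = 1.0), c(n, s, s)) +
    array(rep(px$cti, s * s), c(n, s, s))

  agg <- aggregate_subgrid(hli_sub, lc_sub, cti_sub)
  px$shade_dens <- agg$shade_dens
  px$landcover <- eco_codes[agg$landcover]
  px$cti <- agg$cti  # pixel CTI is defined as the subgrid mean

  out <- list(pixels = px, eco_codes = eco_codes, config = config)
  if (subgrids)
    out$subgrids <- list(hli = hli_sub, landcover = lc_sub, cti = cti_sub)
  out
}

#' Aggregate within-pixel subgrids to pixel-level predictors
#'
#' Shade density is the percent of subgrid cells with HLI <= 0.6 (boundary
#' included), landcover is the modal (majority) code, and CTI is the
#' arithmetic mean, matching the 30-m to 1-km aggregation used for these
#' predictors.
#'
#' @param hli_sub,landcover_sub,cti_sub either matrices (one pixel) or 3D
#'   arrays (pixel x sub x sub).
#' @param hli_threshold HLI value at or below which a subcell counts as
#'   topographically shaded (default 0.6).
#' @return a list with vectors `shade_dens` (percent), `landcover` (modal
#'   code), `cti` (mean).
#' @export
aggregate_subgrid <- function(hli_sub, landcover_sub, cti_sub,
                              hli_threshold = 0.6) {
  as_arr <- function(x) {
    if (is.matrix(x)) array(x, c(1, dim(x))) else x
  }
  h <- as_arr(hli_sub); lc <- as_arr(landcover_sub); ct <- as_arr(cti_sub)
  if (length(h) == 0 || length(lc) == 0 || length(ct) == 0)
    stop("empty subgrid")
  n <- dim(h)[1]
  hm <- matrix(h, nrow = n)
  cm <- matrix(ct, nrow = n)
  lm <- matrix(lc, nrow = n)
  shade <- 100 * rowMeans(hm <= hli_threshold)
  ctim <- rowMeans(cm)
  modal <- apply(lm, 1, function(v) {
    tab <- tabulate(v)
    which.max(tab)  # ties: lowest code, documented
  })
  list(shade_dens = shade, landcover = as.integer(modal), cti = ctim)
}

#' Sensitivity-link coefficients for the synthetic truth table
#'
#' The true moderate-drought sensitivity of a pixel is a clipped linear
#' function of z-scored covariates,
#' `s_mod = clip(b0 + sum_j b_j z(x_j), 0, 0.5)`, and the severe-drought
#' sensitivity is `s_sev = clip(gamma * s_mod + delta, s_mod, 0.6)`.
#' Defaults make elevation and soil bulk density the dominant drivers, with
#' a weaker climatic-water-deficit term, so that attribution models have a
#' known ground truth to recover.
#'
#' @param b0 intercept of the moderate-sensitivity link (fraction).
#' @param betas named numeric vector of coefficients on z-scored covariates.
#' @param gamma,delta severe-drought amplification slope and offset.
#' @return list of class `sensitivity_link`.
#' @export
sensitivity_link <- function(b0 = 0.10,
                             betas = c(elev = 0.06, soil_bd = 0.05,
                                       deficit = 0.02),
                             gamma = 1.3, delta = 0.02) {
  structure(list(b0 = b0, betas = betas, gamma = gamma, delta = delta),
            class = "sensitivity_link")
}

#' Generate the synthetic truth table
#'
#' For each pixel: a baseline summer EVI (driven by AET, so greener where
#' the climate supports more evapotranspiration), true moderate and severe
#' drought sensitivities from the configured [sensitivity_link()], the SPEI
#' timescale the pixel truly responds to, and disturbance / long-term-trend
#' contamination flags.
#'
#' @param pixels pixel data.frame from [simulate_landscape()].
#' @param link a [sensitivity_link()].
#' @param timescales candidate true timescales, sampled uniformly per pixel.
#' @param disturbed_frac,trend_frac fractions of pixels receiving an abrupt
#'   permanent disturbance drop or an additive linear EVI trend.
#' @param trend_slope additive trend, EVI units per year (default 0.01).
#' @param noise_sd lognormal sd of pixel-to-pixel baseline-EVI scatter.
#' @param seed integer seed.
#' @return data.frame with columns `pixel_id`, `baseline_evi_true`,
#'   `s_mod_true`, `s_sev_true`, `true_timescale`, `disturbed_flag`,
#'   `trend_flag`, `trend_slope`.
#' @export
simulate_truth <- function(pixels, link = sensitivity_link(),
                           timescales = c(3, 6, 12),
                           disturbed_frac = 0.05, trend_frac = 0.05,
                           trend_slope = 0.01, noise_sd = 0.03, seed = 1L) {
  stopifnot(inherits(link, "sensitivity_link"))
  set.seed(seed)
  n <- nrow(pixels)
  lin <- rep(link$b0, n)
  for (nm in names(link$betas)) {
    x <- pixels[[nm]]
    if (is.null(x)) stop("truth link refers to missing covariate: ", nm)
    z <- (x - mean(x)) / (sd(x) + (sd(x) == 0))
    lin <- lin + link$betas[[nm]] * z
  }
  s_mod <- pmin(pmax(lin, 0), 0.5)
  s_sev <- pmin(pmax(link$gamma * s_mod + link$delta, s_mod), 0.6)

  aet <- pixels$aet
  base <- 0.15 + 0.55 * (aet - min(aet)) / (diff(range(aet)) + (diff(range(aet)) == 0))
  base <- pmin(pmax(base * exp(rnorm(n, sd = noise_sd)), 0.05), 0.95)

  data.frame(pixel_id = pixels$pixel_id,
             baseline_evi_true = base,
             s_mod_true = s_mod,
             s_sev_true = s_sev,
             true_timescale = sample(timescales, n, replace = TRUE),
             disturbed_flag = runif(n) < disturbed_frac,
             trend_flag = runif(n) < trend_frac,
             trend_slope = trend_slope)
}

#' Generate a pixel table with a known sensitivity-driven response
#'
#' Convenience generator for attribution studies: a synthetic landscape
#' whose drought-sensitivity response (percent) is the truth-link signal
#' (elevation and soil bulk density dominant by default) plus Gaussian
#' noise calibrated so the signal explains a target fraction `r2` of the
#' response variance. Includes a `drought_exp` covariate and the
#' `ecosystem` category so the full 11-predictor roster is available.
#'
#' @param n_rows,n_cols landscape grid dimensions.
#' @param r2 target fraction of response variance explained by the true
#'   signal.
#' @param link a [sensitivity_link()].
#' @param smoothing_length spatial-autocorrelation scale (pixels).
#' @param seed integer seed.
#' @return data.frame of pixels with the 11 standard predictors plus
#'   `s_true` (true signal, percent) and `s_mod_max` (noisy response,
#'   percent); attribute `"sigma"` records the noise sd.
#' @export
simulate_attribution_data <- function(n_rows = 100, n_cols = 100,
                                      r2 = 0.6, link = sensitivity_link(),
                                      smoothing_length = 3, seed = 1L) {
  cr <- landscape_config()$covariate_ranges
  cr$drought_exp <- c(0, 40)
  cfg <- landscape_config(n_rows, n_cols, smoothing_length,
                          subgrid_size = 3, covariate_ranges = cr,
                          seed = seed)
  px <- simulate_landscape(cfg)$pixels
  truth <- simulate_truth(px, link, seed = seed + 1L)
  s_true <- 100 * truth$s_mod_true
  sigma <- sd(s_true) * sqrt((1 - r2) / r2)
  set.seed(seed + 2L)
  px$s_true <- s_true
  px$s_mod_max <- s_true + rnorm(nrow(px), 0, sigma)
  attr(px, "sigma") <- sigma
  px
}
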