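#' Configuration for the synthetic monthly climate generator
#'
#' Monthly precipitation is drawn from a gamma distribution with a seasonal
#' mean cycle (wet winters, dry summers, as in a Mediterranean/maritime
#' climate) and PET follows a seasonal sinusoid peaking in July with
#' Gaussian noise. Forced drought years multiply the precipitation of the
#' 12 months ending in August of the named year by a factor < 1, emulating
#' region-wide meteorological droughts shared across pixels.
#'
#' @param monthly_prcp_mean mean precipitation per calendar month (mm),
#'   length 12 (January first).
#' @param prcp_shape gamma shape of monthly precipitation (larger = less
#'   variable).
#' @param pet_mean,pet_amp mean and seasonal amplitude of monthly PET (mm);
#'   PET for month m is `pet_mean + pet_amp * cos(2*pi*(m - 7)/12)` plus
#'   noise, so it peaks in July.
#' @param pet_sd sd of the monthly PET noise (mm).
#' @param drought_years named numeric vector: names are calendar years,
#'   values are precipitation multipliers applied to the 12 months ending
#'   in August of that year (1 = no forcing).
#' @return list of class `climate_config`.
#' @export
climate_config <- function(monthly_prcp_mean = c(95, 75, 65, 45, 35, 25,
                                                 12, 14, 28, 55, 90, 100),
                           prcp_shape = 2.5,
                           pet_mean = 50, pet_amp = 45, pet_sd = 5,
                           drought_years = c("2001" = 0.70, "2005" = 0.60,
                                             "2012" = 0.75, "2015" = 0.50)) {
  stopifnot(length(monthly_prcp_mean) == 12, all(monthly_prcp_mean > 0),
            prcp_shape > 0, pet_amp <= pet_mean)
  structure(list(monthly_prcp_mean = monthly_prcp_mean,
                 prcp_shape = prcp_shape, pet_mean = pet_mean,
                 pet_amp = pet_amp, pet_sd = pet_sd,
                 drought_years = drought_years),
            class = "climate_config")
}

#' Generate synthetic monthly climate series
#'
#' @param pixel_ids vector of pixel identifiers (one monthly series each).
#' @param years calendar years to cover (complete months are generated for
#'   each); at least 5 years are required for downstream SPEI fitting.
#' @param config a [climate_config()].
#' @param seed integer seed; output is bit-reproducible under it.
#' @return data.frame with columns `pixel_id`, `year`, `month`, `prcp`
#'   (mm), `pet` (mm), ordered by pixel, year, month.
#' @export
simulate_climate <- function(pixel_ids, years, config = climate_config(),
                             seed = 1L) {
  stopifnot(inherits(config, "climate_config"))
  if (length(years) < 5)
    stop("need at least 5 years of climate to fit SPEI")
  set.seed(seed)
  np <- length(pixel_ids); ny <- length(years)
  years <- sort(years)

  month <- rep(rep(1:12, times = ny), times = np)
  year <- rep(rep(years, each = 12), times = np)
  pid <- rep(pixel_ids, each = 12L * ny)

  mu <- config$monthly_prcp_mean[month]
  # drought forcing: multiplier on the mean of the 12 months ending Aug
  fac <- rep(1, length(month))
  for (ystr in names(config$drought_years)) {
    y <- as.integer(ystr)
    f <- config$drought_years[[ystr]]
    sel <- (year == y & month <= 8) | (year == y - 1 & month >= 9)
    fac[sel] <- fac[sel] * f
  }
  prcp <- rgamma(length(mu), shape = config$prcp_shape,
                 scale = mu * fac / config$prcp_shape)
  pet <- pmax(config$pet_mean +
                config$pet_amp * cos(2 * pi * (month - 7) / 12) +
                rnorm(length(month), sd = config$pet_sd), 0)

  data.frame(pixel_id = pid, year = year, month = month,
             prcp = prcp, pet = pet)
}
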