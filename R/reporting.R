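#' Biome-level summary of drought sensitivity
#'
#' Per biome: medians and interquartile ranges of the maximal moderate and
#' severe sensitivities, the Spearman rank correlation between them, the
#' fraction of pixels whose severe-drought sensitivity exceeds their
#' moderate-drought sensitivity with the mean positive excess (percentage
#' points), and the fractions of pixels declining under drought (S' > 0).
#' Quantiles use linear interpolation (type 7) throughout.
#'
#' @param sens sensitivity table from [sensitivity_table()].
#' @param biome character vector of biome labels aligned to `sens` rows.
#' @return data.frame with one row per biome.
#' @export
biome_summary <- function(sens, biome) {
  stopifnot(length(biome) == nrow(sens))
  out <- list()
  for (b in unique(biome)) {
    d <- sens[biome == b & sens$valid_mod & sens$valid_sev, , drop = FALSE]
    if (!nrow(d)) {
      warning("biome '", b, "' has no valid pixels; omitted")
      next
    }
    sm <- d$s_mod_max; sv <- d$s_sev_max
    rho <- if (nrow(d) > 2) suppressWarnings(
      cor(sm, sv, method = "spearman")) else NA_real_
    exceed <- sv > sm
    excess <- if (any(exceed)) mean((sv - sm)[exceed]) else NA_real_
    out[[b]] <- data.frame(
      biome = b, n_pixels = nrow(d),
      median_s_mod = median(sm), median_s_sev = median(sv),
      iqr_mod_lo = unname(quantile(sm, 0.25, type = 7)),
      iqr_mod_hi = unname(quantile(sm, 0.75, type = 7)),
      iqr_sev_lo = unname(quantile(sv, 0.25, type = 7)),
      iqr_sev_hi = unname(quantile(sv, 0.75, type = 7)),
      spearman_mod_sev = rho,
      frac_sev_gt_mod = mean(exceed),
      mean_excess_sev = excess,
      frac_declining_mod = mean(sm > 0),
      frac_declining_sev = mean(sv > 0))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Ecosystem-level summary of baseline EVI and drought sensitivity
#'
#' Per-ecosystem medians and interquartile ranges of baseline EVI (the mean
#' of the per-timescale baselines), `s_mod_max` and `s_sev_max`, plus a
#' per-pixel table assigning each pixel its ecosystem's median
#' sensitivities (the map-product convention: median values assigned to
#' all pixels mapped as that type).
#'
#' @param sens sensitivity table from [sensitivity_table()].
#' @param ecosystem character vector of ecosystem codes aligned to `sens`
#'   rows.
#' @param codes optional vector of known ecosystem codes; labels outside
#'   it raise an error.
#' @return list with `summary` (one row per ecosystem) and `assignment`
#'   (one row per labeled pixel: `pixel_id`, `ecosystem`,
#'   `median_s_mod`, `median_s_sev`).
#' @export
ecosystem_summary <- function(sens, ecosystem, codes = NULL) {
  stopifnot(length(ecosystem) == nrow(sens))
  if (!is.null(codes)) {
    bad <- setdiff(unique(ecosystem), codes)
    if (length(bad)) stop("unknown ecosystem code(s): ",
                          paste(bad, collapse = ", "))
  }
  base_cols <- grep("^baseline_", names(sens), value = TRUE)
  base <- if (length(base_cols))
    rowMeans(sens[base_cols], na.rm = TRUE) else rep(NA_real_, nrow(sens))
  rows <- list()
  for (e in sort(unique(ecosystem))) {
    i <- ecosystem == e & sens$valid_mod & sens$valid_sev
    if (!any(i)) next
    q <- function(v, p) unname(quantile(v, p, type = 7, na.rm = TRUE))
    rows[[e]] <- data.frame(
      ecosystem = e, n_pixels = sum(i),
      median_baseline = median(base[i], na.rm = TRUE),
      iqr_baseline_lo = q(base[i], 0.25), iqr_baseline_hi = q(base[i], 0.75),
      median_s_mod = median(sens$s_mod_max[i]),
      iqr_mod_lo = q(sens$s_mod_max[i], 0.25),
      iqr_mod_hi = q(sens$s_mod_max[i], 0.75),
      median_s_sev = median(sens$s_sev_max[i]),
      iqr_sev_lo = q(sens$s_sev_max[i], 0.25),
      iqr_sev_hi = q(sens$s_sev_max[i], 0.75))
  }
  summ <- do.call(rbind, c(rows, make.row.names = FALSE))
  idx <- match(ecosystem, summ$ecosystem)
  assignment <- data.frame(pixel_id = sens$pixel_id,
                           ecosystem = ecosystem,
                           median_s_mod = summ$median_s_mod[idx],
                           median_s_sev = summ$median_s_sev[idx])
  list(summary = summ, assignment = assignment)
}

#' Two-dimensional histogram of moderate vs severe sensitivity
#'
#' Density-plot data on fixed breaks, mirroring biome-level density plots
#' of S'_mod against S'_sev.
#'
#' @param sens sensitivity table.
#' @param breaks number of bins per axis.
#' @return list with `breaks_mod`, `breaks_sev` and `counts` matrix.
#' @export
sensitivity_density <- function(sens, breaks = 50) {
  d <- sens[sens$valid_mod & sens$valid_sev, ]
  bx <- seq(min(d$s_mod_max), max(d$s_mod_max), length.out = breaks + 1)
  by <- seq(min(d$s_sev_max), max(d$s_sev_max), length.out = breaks + 1)
  ix <- pmin(findInterval(d$s_mod_max, bx, rightmost.closed = TRUE), breaks)
  iy <- pmin(findInterval(d$s_sev_max, by, rightmost.closed = TRUE), breaks)
  counts <- matrix(0L, breaks, breaks)
  for (k in seq_along(ix))
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  list(breaks_mod = bx, breaks_sev = by, counts = counts)
}
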