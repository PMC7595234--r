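#' Pipeline run configuration
#'
#' Bundles the stage configurations and the output contract of a full run:
#' simulate -> SPEI -> EVI -> sensitivity -> screening -> attribution (one
#' model per roster entry) -> report. The default roster is the four-model
#' protocol: each combination of drought-intensity level (moderate,
#' severe) and biome (forest, shrub-steppe).
#'
#' @param out_dir directory for stage outputs and the manifest.
#' @param seed global seed; stage seeds are derived from it via
#'   [stage_seed()].
#' @param landscape a [landscape_config()] (its `seed` is overridden by
#'   the derived stage seed).
#' @param climate_years,evi_years calendar year ranges.
#' @param climate a [climate_config()].
#' @param link a [sensitivity_link()] for the synthetic truth.
#' @param spei a [spei_config()].
#' @param sensitivity a [sensitivity_config()].
#' @param trend_alpha Mann-Kendall significance level.
#' @param exposure_period,exposure_timescale,exposure_threshold cumulative
#'   drought-exposure definition.
#' @param brt a [brt_params()].
#' @param roster data.frame with columns `biome`, `intensity` (values
#'   `"mod"`/`"sev"`).
#' @param n_runs,sample_size BRT ensemble protocol.
#' @param predictors predictor columns for attribution.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("droughtsense_run_"),
                            seed = 1L,
                            landscape = landscape_config(),
                            climate_years = 1985:2016,
                            evi_years = 2000:2016,
                            climate = climate_config(),
                            link = sensitivity_link(),
                            spei = spei_config(),
                            sensitivity = sensitivity_config(),
                            trend_alpha = 0.05,
                            exposure_period = 1990:2016,
                            exposure_timescale = 12,
                            exposure_threshold = -1,
                            brt = brt_params(),
                            roster = expand.grid(
                              biome = c("forest", "shrub-steppe"),
                              intensity = c("mod", "sev"),
                              stringsAsFactors = FALSE),
                            n_runs = 20, sample_size = 10000,
                            predictors = c("elev", "aet", "deficit",
                                           "soil_awc", "soil_bd", "wtd",
                                           "cti", "hli", "shade_dens",
                                           "drought_exp", "ecosystem")) {
  if (!nrow(roster)) stop("model roster is empty")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 landscape = landscape, climate_years = climate_years,
                 evi_years = evi_years, climate = climate, link = link,
                 spei = spei, sensitivity = sensitivity,
                 trend_alpha = trend_alpha,
                 exposure_period = exposure_period,
                 exposure_timescale = exposure_timescale,
                 exposure_threshold = exposure_threshold,
                 brt = brt, roster = roster, n_runs = n_runs,
                 sample_size = sample_size, predictors = predictors),
            class = "pipeline_config")
}

#' Derive a stage seed from the global seed
#'
#' Stage seeds are `(seed * 48271 + hash(stage) * 8191 + run) mod
#' (2^31 - 1)` with a polynomial string hash of the stage name, so no two
#' stages reuse a seed and the whole pipeline is reproducible from the one
#' global seed.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @param run run index (default 0).
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage, run = 0) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  s <- ((seed %% m) * 48271) %% m
  s <- (s + (h * 8191) %% m + run) %% m
  as.integer(max(s, 1))
}

# cheap deterministic string hash for the manifest config fingerprint
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 12,
                        force = TRUE)
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Read a validated CSV table
#'
#' @param path file path.
#' @param schema named character vector mapping required column names to
#'   types (`"integer"`, `"numeric"`, `"character"`, `"logical"`).
#' @return data.frame with exactly the schema columns, coerced.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(names(schema), names(df))
  extra <- setdiff(names(df), names(schema))
  if (length(missing) || length(extra)) {
    msg <- c(
      if (length(missing)) paste("missing required column(s):",
                                 paste(missing, collapse = ", ")),
      if (length(extra)) paste("unexpected column(s):",
                               paste(extra, collapse = ", ")))
    stop(paste(msg, collapse = "; "))
  }
  for (nm in names(schema)) {
    df[[nm]] <- switch(schema[[nm]],
                       integer = as.integer(df[[nm]]),
                       numeric = as.numeric(df[[nm]]),
                       character = as.character(df[[nm]]),
                       logical = as.logical(df[[nm]]),
                       stop("unknown schema type ", schema[[nm]]))
  }
  df[names(schema)]
}

#' Write a CSV table (UTF-8, comma-delimited, "." decimal)
#'
#' @param df data.frame.
#' @param path file path; parent directories are created.
#' @return the path, invisibly.
#' @export
write_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full drought-sensitivity pipeline
#'
#' Executes simulate -> SPEI -> EVI -> sensitivity -> screening ->
#' attribution (per roster entry) -> report, writing each stage's table to
#' `out_dir` and a JSON manifest recording the config fingerprint, derived
#' seeds, row counts per stage, and output files. With `resume = TRUE`,
#' stages whose output file already exists are read back instead of
#' recomputed, so deleting an intermediate file regenerates only that
#' stage and those downstream.
#'
#' @param config a [pipeline_config()].
#' @param resume reuse existing stage outputs (default `FALSE`).
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly; all outputs are under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, resume = FALSE, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  pth <- function(f) file.path(config$out_dir, f)
  counts <- list()
  seeds <- list()
  outputs <- character(0)

  stage <- function(name, file, schema, compute) {
    p <- pth(file)
    if (resume && file.exists(p)) {
      say("reusing ", file)
      df <- read_table(p, schema)
    } else {
      say("computing ", file)
      df <- compute()
      write_table(df, p)
    }
    counts[[name]] <<- nrow(df)
    outputs <<- c(outputs, file)
    df
  }

  # --- simulate ---------------------------------------------------------
  ls_cfg <- config$landscape
  ls_cfg$seed <- stage_seed(config$seed, "landscape")
  seeds$landscape <- ls_cfg$seed
  pix_schema <- c(pixel_id = "integer", row = "integer", col = "integer",
                  elev = "numeric", aet = "numeric", deficit = "numeric",
                  soil_awc = "numeric", soil_bd = "numeric",
                  wtd = "numeric", cti = "numeric", hli = "numeric",
                  biome = "character", ecosystem = "character",
                  shade_dens = "numeric", landcover = "character")
  pixels <- stage("pixels", "pixels.csv", pix_schema, function() {
    simulate_landscape(ls_cfg)$pixels[names(pix_schema)]
  })

  seeds$truth <- stage_seed(config$seed, "truth")
  truth_schema <- c(pixel_id = "integer", baseline_evi_true = "numeric",
                    s_mod_true = "numeric", s_sev_true = "numeric",
                    true_timescale = "integer",
                    disturbed_flag = "logical", trend_flag = "logical",
                    trend_slope = "numeric")
  truth <- stage("truth", "truth.csv", truth_schema, function() {
    simulate_truth(pixels, config$link, seed = seeds$truth)
  })

  seeds$climate <- stage_seed(config$seed, "climate")
  clim_schema <- c(pixel_id = "integer", year = "integer",
                   month = "integer", prcp = "numeric", pet = "numeric")
  climate <- stage("climate", "climate.csv", clim_schema, function() {
    simulate_climate(pixels$pixel_id, config$climate_years,
                     config$climate, seed = seeds$climate)
  })

  # --- spei -------------------------------------------------------------
  spei_schema <- c(pixel_id = "integer", year = "integer",
                   timescale = "integer", spei = "numeric",
                   drought_class = "character")
  spei_tab <- stage("spei", "spei.csv", spei_schema, function() {
    st <- compute_spei(climate, config$spei)
    st$drought_class <- as.character(st$drought_class)
    st
  })

  seeds$evi <- stage_seed(config$seed, "evi")
  evi_schema <- c(pixel_id = "integer", year = "integer",
                  evi_summer = "numeric")
  evi <- stage("evi", "evi.csv", evi_schema, function() {
    simulate_evi(truth, spei_tab, config$evi_years, seed = seeds$evi)
  })

  # --- sensitivity ------------------------------------------------------
  sens_file <- "sensitivity.csv"
  p_sens <- pth(sens_file)
  if (resume && file.exists(p_sens)) {
    sens <- read.csv(p_sens)
  } else {
    sens <- sensitivity_table(evi, spei_tab, config$sensitivity)
    write_table(sens, p_sens)
  }
  counts$sensitivity <- nrow(sens)
  outputs <- c(outputs, sens_file)

  # --- screening --------------------------------------------------------
  trends <- trend_screen(evi, config$trend_alpha)
  scr <- apply_exclusions(pixels,
                          truth$disturbed_flag[match(pixels$pixel_id,
                                                     truth$pixel_id)],
                          trends$trend_flag[match(pixels$pixel_id,
                                                  trends$pixel_id)])
  write_table(data.frame(rule = names(scr$ledger),
                         n = as.integer(scr$ledger)),
              pth("exclusion_ledger.csv"))
  outputs <- c(outputs, "exclusion_ledger.csv")
  counts$retained <- nrow(scr$retained)

  expo <- drought_exposure(spei_tab, config$exposure_period,
                           config$exposure_timescale,
                           config$exposure_threshold)

  # merged modeling table
  keep <- scr$retained$pixel_id
  tab <- scr$retained
  tab$drought_exp <- expo$drought_exp[match(tab$pixel_id, expo$pixel_id)]
  si <- match(tab$pixel_id, sens$pixel_id)
  tab$s_mod_max <- sens$s_mod_max[si]
  tab$s_sev_max <- sens$s_sev_max[si]
  tab$valid_mod <- sens$valid_mod[si]
  tab$valid_sev <- sens$valid_sev[si]
  write_table(tab, pth("model_table.csv"))
  outputs <- c(outputs, "model_table.csv")
  counts$model_table <- nrow(tab)

  # --- attribution ------------------------------------------------------
  models <- list()
  for (i in seq_len(nrow(config$roster))) {
    b <- config$roster$biome[i]
    int <- config$roster$intensity[i]
    resp <- paste0("s_", int, "_max")
    vflag <- paste0("valid_", int)
    d <- tab[tab$biome == b & tab[[vflag]], , drop = FALSE]
    tag <- paste0(gsub("[^a-z]", "_", b), "_", int)
    seeds[[paste0("brt_", tag)]] <- stage_seed(config$seed, "brt", i)
    ens <- brt_ensemble(d, resp, config$predictors, config$brt,
                        n_runs = config$n_runs,
                        sample_size = min(config$sample_size, nrow(d)),
                        seed = seeds[[paste0("brt_", tag)]])
    write_table(ens$influence_summary,
                pth(paste0("influence_", tag, ".csv")))
    write_table(ens$cv_stats, pth(paste0("cv_stats_", tag, ".csv")))
    pd_long <- do.call(rbind, lapply(names(ens$pd), function(p) {
      d <- ens$pd[[p]]
      data.frame(predictor = p, value = as.character(d$value),
                 mean = d$mean, q25 = d$q25, q75 = d$q75)
    }))
    write_table(pd_long, pth(paste0("partial_dependence_", tag, ".csv")))
    outputs <- c(outputs, paste0(c("influence_", "cv_stats_",
                                   "partial_dependence_"), tag, ".csv"))
    models[[tag]] <- list(
      biome = b, intensity = int, n_rows = nrow(d),
      cv_correlation = unname(ens$cv_summary$cv_correlation["median"]),
      pct_deviance_explained =
        unname(ens$cv_summary$pct_deviance_explained["median"]))
  }

  # --- report -----------------------------------------------------------
  sens_kept <- sens[match(keep, sens$pixel_id), ]
  bs <- biome_summary(sens_kept, tab$biome)
  write_table(bs, pth("biome_summary.csv"))
  es <- ecosystem_summary(sens_kept, tab$ecosystem)
  write_table(es$summary, pth("ecosystem_summary.csv"))
  write_table(es$assignment, pth("ecosystem_assignment.csv"))
  outputs <- c(outputs, "biome_summary.csv", "ecosystem_summary.csv",
               "ecosystem_assignment.csv")

  manifest <- list(config_hash = config_hash(unclass(config)[
    setdiff(names(config), "out_dir")]),
    seed = config$seed, seeds = seeds, row_counts = counts,
    models = models, outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys match the arguments of
#' [pipeline_config()] (scalar settings and year ranges; nested stage
#' configs use the constructors' argument names). An optional `seed`
#' argument overrides the file.
#'
#' @param path YAML file.
#' @param seed optional seed override.
#' @return a [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  if (!is.null(seed)) args$seed <- seed
  else if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$climate_years))
    args$climate_years <- y$climate_years[1]:y$climate_years[2]
  if (!is.null(y$evi_years))
    args$evi_years <- y$evi_years[1]:y$evi_years[2]
  if (!is.null(y$landscape))
    args$landscape <- do.call(landscape_config, y$landscape)
  if (!is.null(y$spei)) args$spei <- do.call(spei_config, y$spei)
  if (!is.null(y$sensitivity))
    args$sensitivity <- do.call(sensitivity_config, y$sensitivity)
  if (!is.null(y$brt)) args$brt <- do.call(brt_params, y$brt)
  for (nm in c("trend_alpha", "n_runs", "sample_size", "predictors"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(pipeline_config, args)
}
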