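#' Run the full evaporation analysis in memory
#'
#' Ties the stages together exactly as the field analysis does: tower QC
#' (gap filling and negative-daytime-LE screening), temperature-optimum
#' estimation, per-day PT-JPL scenes holding the daily NDVI constant
#' through the daytime hours, conversion to water depths, daily/field
#' aggregation, Savitzky-Golay smoothing, cumulative budgets and
#' underperformance mapping.
#'
#' @param stack An [ndvi_stack()].
#' @param records Hourly tower records (from [read_met_csv()] or
#'   [gen_tower_record()]).
#' @param boundary A [field_boundary()].
#' @param params A [ptjpl_params()] object; `topt` is replaced by the
#'   seasonal estimate unless `estimate_topt. = FALSE`.
#' @param season Length-2 sowing/harvest dates; defaults to the stack's
#'   date range.
#' @param longitude Site longitude (degrees east) for solar time.
#' @param tz_offset Timezone UTC offset (hours); defaults to the records'
#'   `tz_offset` attribute, else 0.
#' @param irrigation Optional data frame `date`, `depth_mm`.
#' @param include_irrigation Add irrigation to the cumulative water curve.
#' @param smooth_window,smooth_polyorder Savitzky-Golay settings (days /
#'   degree).
#' @param tower_pixel Integer `(row, col)` of the tower pixel; defaults to
#'   the grid centre. Used for the temperature optimum and the
#'   tower-pixel evaluation mode.
#' @param k_underperf Standard-deviation multiplier of the
#'   underperformance threshold.
#' @param estimate_topt. Estimate `topt` from the season (default) or keep
#'   `params$topt`.
#' @param gap_fill_fields Columns gap-filled before the run.
#' @return Object of class `fieldet_run`: a list with the QC log, the
#'   daily field series, hourly modeled and closure-corrected tower
#'   series (mm/h), daily E grids, the cumulative map and series, the
#'   underperformance mask, and the parameters/season used.
#' @export
run_pipeline <- function(stack, records, boundary,
                         params = ptjpl_params(),
                         season = NULL,
                         longitude = 0,
                         tz_offset = NULL,
                         irrigation = NULL,
                         include_irrigation = TRUE,
                         smooth_window = 15,
                         smooth_polyorder = 3,
                         tower_pixel = NULL,
                         k_underperf = 1.5,
                         estimate_topt. = TRUE,
                         gap_fill_fields = c("Ta", "RH", "Rn", "G", "H",
                                             "LE")) {
  if (is.null(tz_offset)) {
    tz_offset <- attr(records, "tz_offset")
    if (is.null(tz_offset)) tz_offset <- 0
  }
  qc <- list(n_filled = integer(0), n_screened = 0L)
  for (f in intersect(gap_fill_fields, names(records))) {
    if (any(is.na(records[[f]]))) {
      records <- gap_fill_linear(records, f)
      qc$n_filled[f] <- attr(records, "n_filled")
    }
  }
  records <- screen_negative_daytime_le(records)
  qc$n_screened <- attr(records, "n_screened")

  dims <- dim(stack$grids)
  if (is.null(tower_pixel)) tower_pixel <- as.integer(ceiling(dims[1:2] / 2))
  ndvi_tower <- data.frame(date = stack$dates,
                           ndvi = stack$grids[tower_pixel[1],
                                              tower_pixel[2], ])
  if (estimate_topt.) {
    params$topt <- estimate_topt(records, ndvi_tower, params)
  }
  f_apar_max <- fapar_max_grid(stack, params)

  if (is.null(season)) season <- range(stack$dates)
  season <- as.Date(season)
  day <- daytime_mask(records)
  rec_dates <- as.Date(records$timestamp)
  run_dates <- stack$dates[stack$dates %in% rec_dates[day]]
  if (length(run_dates) == 0L) {
    stop("run_pipeline: no dates with both NDVI and daytime meteorology",
         call. = FALSE)
  }

  zmask <- zonal_mean(stack$grids[, , 1], stack$geotransform, boundary)$mask
  daily_grids <- array(NA_real_, c(dims[1], dims[2], length(run_dates)))
  hour_ts <- list()
  hour_field <- list()
  hour_tower <- list()
  for (i in seq_along(run_dates)) {
    scene <- run_scene(stack, run_dates[i], records, params, f_apar_max,
                       longitude, tz_offset)
    dgrid <- matrix(0, dims[1], dims[2])
    ef <- et <- numeric(length(scene$hours))
    for (h in seq_along(scene$hours)) {
      e_h <- flux_to_depth(scene$fluxes[[h]]$le_total, params$lambda_v)
      dgrid <- dgrid + e_h
      ef[h] <- mean(e_h[zmask])
      et[h] <- e_h[tower_pixel[1], tower_pixel[2]]
    }
    daily_grids[, , i] <- dgrid
    hour_ts[[i]] <- scene$hours
    hour_field[[i]] <- ef
    hour_tower[[i]] <- et
  }
  hourly_model <- data.frame(
    timestamp = do.call(c, hour_ts),
    E_field = unlist(hour_field),
    E_tower_pixel = unlist(hour_tower))

  field_mean <- apply(daily_grids, 3, function(g) mean(g[zmask]))
  field_std <- apply(daily_grids, 3, function(g) stats::sd(g[zmask]))
  precip <- tapply(records$P, rec_dates, function(p) sum(p, na.rm = TRUE))
  daily <- data.frame(date = run_dates,
                      E_mm = field_mean,
                      E_smooth = NA_real_,
                      pixel_std = field_std,
                      precip_mm = as.numeric(precip[format(run_dates)]),
                      irrigation_mm = 0)
  daily$precip_mm[is.na(daily$precip_mm)] <- 0
  if (!is.null(irrigation) && nrow(irrigation) > 0) {
    m <- match(as.Date(irrigation$date), daily$date)
    ok <- !is.na(m)
    daily$irrigation_mm[m[ok]] <- daily$irrigation_mm[m[ok]] +
      irrigation$depth_mm[ok]
  }
  if (nrow(daily) >= smooth_window) {
    daily$E_smooth <- smooth_series(daily$E_mm, smooth_window,
                                    smooth_polyorder)
  } else {
    warning("run_pipeline: series shorter than the smoothing window; ",
            "E_smooth left NA")
  }

  cumulative <- cumulative_compare(daily, season, include_irrigation)
  cum_map <- cumulative_e_map(daily_grids, run_dates, season)
  under <- underperformance_mask(cum_map, stack$geotransform, boundary,
                                 k_underperf)

  le_corr <- closure_correct(records)
  tower_e <- data.frame(timestamp = records$timestamp,
                        E = flux_to_depth(le_corr, params$lambda_v))

  structure(list(qc = qc,
                 params = params,
                 season = season,
                 daily = daily,
                 daily_grids = daily_grids,
                 daily_dates = run_dates,
                 hourly_model = hourly_model,
                 tower_e = tower_e,
                 daytime = data.frame(timestamp = records$timestamp,
                                      mask = day),
                 cumulative = cumulative,
                 cumulative_map = cum_map,
                 underperformance = under,
                 geotransform = stack$geotransform,
                 boundary = boundary,
                 tower_pixel = tower_pixel,
                 records = records),
            class = "fieldet_run")
}

#' @export
print.fieldet_run <- function(x, ...) {
  cat(sprintf("fieldET run: %d days, topt = %.1f degC\n",
              nrow(x$daily), x$params$topt))
  cat(sprintf("  season %s .. %s; mean daily E = %.2f mm/day\n",
              format(x$season[1]), format(x$season[2]),
              mean(x$daily$E_mm, na.rm = TRUE)))
  cat(sprintf("  QC: %d gap-filled, %d negative daytime LE screened\n",
              sum(x$qc$n_filled), x$qc$n_screened))
  invisible(x)
}

#' Evaluate a pipeline run against the closure-corrected tower
#'
#' Pairs the modeled hourly evaporation (field mean by default, matching
#' a tower that integrates over the field; or the single tower pixel)
#' with the residual-corrected tower evaporation over daytime, in-season
#' hours and computes the performance statistics.
#'
#' @param run A `fieldet_run` from [run_pipeline()].
#' @param mode `"field_mean"` or `"tower_pixel"`.
#' @param season Overrides the run's season if given.
#' @return An `eval_stats` object (see [compute_stats()]) with the pairs
#'   attached as attribute `pairs`.
#' @export
evaluate_run <- function(run, mode = c("field_mean", "tower_pixel"),
                         season = NULL) {
  mode <- match.arg(mode)
  if (is.null(season)) season <- run$season
  model <- data.frame(timestamp = run$hourly_model$timestamp,
                      E = if (mode == "field_mean") {
                        run$hourly_model$E_field
                      } else {
                        run$hourly_model$E_tower_pixel
                      })
  pairs <- pair_series(model, run$tower_e, season, run$daytime)
  stats <- compute_stats(pairs)
  attr(stats, "pairs") <- pairs
  stats
}

#' Bundled 2019 management log for the three UNL ENREC AmeriFlux sites
#'
#' Sowing/harvest dates, growing-season and total rainfall, and irrigation
#' events for US-Ne1, US-Ne2 and US-Ne3 (Eastern Nebraska Research and
#' Extension Center), as recorded in the sites' 2019 management logs.
#'
#' @param sites_path,irrigation_path Optional overrides of the bundled
#'   CSVs (columns: see the files under `extdata/`).
#' @return List with data frames `sites` (site, latitude, longitude, crop,
#'   sowing_date, harvest_date, rainfall_total_mm, rainfall_season_mm) and
#'   `irrigation` (site, date, depth_mm).
#' @export
read_management_log <- function(sites_path = NULL, irrigation_path = NULL) {
  if (is.null(sites_path)) {
    sites_path <- system.file("extdata", "enrec2019_sites.csv",
                              package = "fieldET", mustWork = TRUE)
  }
  if (is.null(irrigation_path)) {
    irrigation_path <- system.file("extdata", "enrec2019_irrigation.csv",
                                   package = "fieldET", mustWork = TRUE)
  }
  sites <- utils::read.csv(sites_path)
  sites$sowing_date <- as.Date(sites$sowing_date)
  sites$harvest_date <- as.Date(sites$harvest_date)
  irrigation <- utils::read.csv(irrigation_path)
  irrigation$date <- as.Date(irrigation$date)
  list(sites = sites, irrigation = irrigation)
}

#' Write a synthetic dataset to disk
#'
#' Materializes a [gen_synthetic_dataset()] as the package's external
#' formats: per-day ASCII NDVI grids, an AmeriFlux-style tower CSV, a
#' GeoJSON boundary, a truth CSV and a JSON manifest with the seed and
#' MD5 checksums of every file.
#'
#' @param config A [synthetic_config()].
#' @param outdir Output directory (created if needed).
#' @param params A [ptjpl_params()] object.
#' @return The manifest as a list, invisibly. Files written: `ndvi/`,
#'   `tower.csv`, `boundary.geojson`, `truth.csv`, `manifest.json`.
#' @export
cmd_simulate <- function(config = synthetic_config(), outdir,
                         params = ptjpl_params()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, mode = 2) != 0) {
    stop("cmd_simulate: output directory is not writable", call. = FALSE)
  }
  ds <- gen_synthetic_dataset(config, params)
  ndvi_paths <- write_ndvi_stack(ds$stack, file.path(outdir, "ndvi"))
  write_met_csv(ds$records, file.path(outdir, "tower.csv"))
  write_boundary(ds$boundary, file.path(outdir, "boundary.geojson"))
  tr <- ds$truth
  truth_df <- data.frame(
    TIMESTAMP_START = format(tr$timestamp, "%Y%m%d%H%M", tz = "UTC"),
    LE_S = sprintf("%.17g", tr$le_s),
    LE_C = sprintf("%.17g", tr$le_c),
    LE_I = sprintf("%.17g", tr$le_i),
    LE_TOTAL = sprintf("%.17g", tr$le_total),
    GAP = sprintf("%.17g", tr$gap_series))
  utils::write.csv(truth_df, file.path(outdir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- c(ndvi_paths,
             file.path(outdir, c("tower.csv", "boundary.geojson",
                                 "truth.csv")))
  manifest <- list(
    seed = config$seed,
    homogeneous_field = config$n_patches == 0,
    topt = tr$topt,
    f_apar_max_tower = tr$f_apar_max,
    files = as.list(setNames(unname(tools::md5sum(files)),
                             sub(paste0("^", outdir, "/?"), "", files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the analysis from files on disk
#'
#' Disk-facing wrapper around [run_pipeline()]: reads the tower CSV, NDVI
#' grid directory and GeoJSON boundary, runs the pipeline, and writes the
#' daily field series, cumulative series, hourly model series, cumulative
#' evaporation map, underperformance mask and a QC log.
#'
#' @param met_csv Path to the AmeriFlux-style tower CSV.
#' @param ndvi_dir Directory of per-day `ndvi_YYYY-MM-DD.asc` grids.
#' @param boundary_path GeoJSON field boundary.
#' @param outdir Output directory.
#' @param irrigation_csv Optional CSV `date`, `depth_mm`.
#' @param tz_offset,rh_unit Passed to [read_met_csv()].
#' @param ... Further arguments to [run_pipeline()] (`params`, `season`,
#'   `longitude`, `smooth_window`, ...).
#' @return The `fieldet_run` object, invisibly.
#' @export
cmd_run <- function(met_csv, ndvi_dir, boundary_path, outdir,
                    irrigation_csv = NULL, tz_offset = 0,
                    rh_unit = "percent", ...) {
  records <- read_met_csv(met_csv, tz_offset = tz_offset, rh_unit = rh_unit)
  stack <- read_ndvi_stack(ndvi_dir)
  boundary <- read_boundary(boundary_path)
  irrigation <- if (!is.null(irrigation_csv)) {
    irr <- utils::read.csv(irrigation_csv)
    irr$date <- as.Date(irr$date)
    irr
  }
  run <- run_pipeline(stack, records, boundary, tz_offset = tz_offset,
                      irrigation = irrigation, ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  num <- function(x) sprintf("%.17g", x)
  daily <- run$daily
  daily_out <- data.frame(date = format(daily$date),
                          E_mm = num(daily$E_mm),
                          E_smooth = num(daily$E_smooth),
                          pixel_std = num(daily$pixel_std),
                          precip_mm = num(daily$precip_mm),
                          irrigation_mm = num(daily$irrigation_mm))
  utils::write.csv(daily_out, file.path(outdir, "daily_series.csv"),
                   row.names = FALSE, quote = FALSE)
  cum_out <- data.frame(date = format(run$cumulative$date),
                        cum_E = num(run$cumulative$cum_E),
                        cum_P = num(run$cumulative$cum_P))
  utils::write.csv(cum_out, file.path(outdir, "cumulative.csv"),
                   row.names = FALSE, quote = FALSE)
  hm <- run$hourly_model
  hm_out <- data.frame(
    TIMESTAMP_START = format(hm$timestamp, "%Y%m%d%H%M", tz = "UTC"),
    E_FIELD = num(hm$E_field),
    E_TOWER_PIXEL = num(hm$E_tower_pixel))
  utils::write.csv(hm_out, file.path(outdir, "hourly_model.csv"),
                   row.names = FALSE, quote = FALSE)
  write_ascii_grid(run$cumulative_map,
                   file.path(outdir, "cumulative_e.asc"), run$geotransform)
  write_ascii_grid(run$underperformance + 0,
                   file.path(outdir, "underperformance_mask.asc"),
                   run$geotransform)
  jsonlite::write_json(
    list(n_gap_filled = as.list(run$qc$n_filled),
         n_negative_daytime_le_screened = run$qc$n_screened,
         topt = run$params$topt,
         season = format(run$season)),
    file.path(outdir, "qc_log.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run)
}

#' Evaluate a finished run directory against its tower CSV
#'
#' Reads the hourly model series written by [cmd_run()] together with the
#' tower CSV, applies the residual closure correction, pairs daytime
#' in-season hours and writes `evaluation.csv`.
#'
#' @param outdir Directory written by [cmd_run()].
#' @param met_csv Tower CSV path.
#' @param season Length-2 sowing/harvest dates; `NULL` keeps all dates.
#' @param mode `"field_mean"` or `"tower_pixel"`.
#' @param tz_offset,rh_unit Passed to [read_met_csv()].
#' @param site Label written into the report.
#' @param lambda_v Latent heat of vaporization (J/kg).
#' @return The `eval_stats` object, invisibly.
#' @export
cmd_evaluate <- function(outdir, met_csv, season = NULL,
                         mode = c("field_mean", "tower_pixel"),
                         tz_offset = 0, rh_unit = "percent",
                         site = "site", lambda_v = 2.26e6) {
  mode <- match.arg(mode)
  records <- read_met_csv(met_csv, tz_offset = tz_offset, rh_unit = rh_unit)
  hm <- utils::read.csv(file.path(outdir, "hourly_model.csv"))
  ts <- as.POSIXct(sprintf("%012.0f", as.numeric(hm$TIMESTAMP_START)),
                   format = "%Y%m%d%H%M", tz = "UTC")
  model <- data.frame(timestamp = ts,
                      E = if (mode == "field_mean") hm$E_FIELD
                          else hm$E_TOWER_PIXEL)
  tower <- data.frame(timestamp = records$timestamp,
                      E = flux_to_depth(closure_correct(records), lambda_v))
  daytime <- data.frame(timestamp = records$timestamp,
                        mask = daytime_mask(records))
  pairs <- pair_series(model, tower, season, daytime)
  st <- compute_stats(pairs)
  rep_df <- data.frame(site = site, n = st$n,
                       r2 = st$r2, bias = st$bias,
                       bias_norm = st$bias_norm, mae = st$mae)
  utils::write.csv(rep_df, file.path(outdir, "evaluation.csv"),
                   row.names = FALSE, quote = FALSE)
  pr <- data.frame(
    TIMESTAMP_START = format(pairs$timestamp, "%Y%m%d%H%M", tz = "UTC"),
    MEASURED = sprintf("%.17g", pairs$x),
    MODELED = sprintf("%.17g", pairs$y))
  utils::write.csv(pr, file.path(outdir, "paired_samples.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(st)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `run` (the
#' analysis), `evaluate` (performance statistics), `report` (print a
#' finished run's summary). Typical use from a shell:
#' `Rscript -e 'fieldET::fieldET_cli()' simulate --outdir scene --seed 7`.
#' Options shared by the subcommands: `--config` (JSON file whose keys
#' override the defaults of the underlying functions), `--seed`,
#' `--outdir`, `--window`, `--polyorder`, `--log-level`.
#'
#' @param args Character vector of arguments; defaults to the command
#'   line.
#' @return Exit-style integer status, invisibly (0 on success).
#' @export
fieldET_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: fieldET <simulate|run|evaluate|report> [options]\n")
    return(invisible(1L))
  }
  sub <- args[1]
  rest <- args[-1]
  opts <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--outdir", type = "character", default = "out"),
    optparse::make_option("--window", type = "integer", default = 15L),
    optparse::make_option("--polyorder", type = "integer", default = 3L),
    optparse::make_option("--log-level", type = "character",
                          default = "info", dest = "log_level")
  )
  parsed <- optparse::parse_args(
    optparse::OptionParser(option_list = opts), args = rest)
  cfg <- if (!is.null(parsed$config)) {
    jsonlite::read_json(parsed$config, simplifyVector = TRUE)
  } else list()
  say <- function(...) {
    if (!identical(parsed$log_level, "quiet")) message(...)
  }
  status <- 0L
  if (sub == "simulate") {
    sc_args <- cfg[intersect(names(cfg),
                             names(formals(synthetic_config)))]
    if (!is.null(parsed$seed)) sc_args$seed <- parsed$seed
    config <- do.call(synthetic_config, sc_args)
    cmd_simulate(config, parsed$outdir)
    say("wrote synthetic dataset to ", parsed$outdir)
  } else if (sub == "run") {
    needed <- c("met_csv", "ndvi_dir", "boundary")
    if (!all(needed %in% names(cfg))) {
      stop("fieldET run: --config must provide ",
           paste(needed, collapse = ", "), call. = FALSE)
    }
    pp_args <- cfg[intersect(names(cfg), names(formals(ptjpl_params)))]
    params <- do.call(ptjpl_params, pp_args)
    run <- cmd_run(cfg$met_csv, cfg$ndvi_dir, cfg$boundary, parsed$outdir,
                   irrigation_csv = cfg$irrigation_csv,
                   tz_offset = cfg$tz_offset %||% 0,
                   rh_unit = cfg$rh_unit %||% "percent",
                   params = params,
                   season = if (!is.null(cfg$season)) as.Date(cfg$season),
                   longitude = cfg$longitude %||% 0,
                   smooth_window = parsed$window,
                   smooth_polyorder = parsed$polyorder)
    say(sprintf("run complete: %d days, QC filled %d / screened %d",
                nrow(run$daily), sum(run$qc$n_filled), run$qc$n_screened))
  } else if (sub == "evaluate") {
    if (is.null(cfg$met_csv)) {
      stop("fieldET evaluate: --config must provide met_csv", call. = FALSE)
    }
    st <- cmd_evaluate(parsed$outdir, cfg$met_csv,
                       season = if (!is.null(cfg$season)) as.Date(cfg$season),
                       mode = cfg$mode %||% "field_mean",
                       tz_offset = cfg$tz_offset %||% 0,
                       rh_unit = cfg$rh_unit %||% "percent",
                       site = cfg$site %||% "site")
    say(sprintf("n = %d, r2 = %.3f, bias = %.4f, MAE = %.4f",
                st$n, st$r2, st$bias, st$mae))
  } else if (sub == "report") {
    ev <- file.path(parsed$outdir, "evaluation.csv")
    dl <- file.path(parsed$outdir, "daily_series.csv")
    if (file.exists(ev)) print(utils::read.csv(ev))
    if (file.exists(dl)) {
      d <- utils::read.csv(dl)
      cat(sprintf("%d days; mean E = %.2f mm/day; total E = %.1f mm\n",
                  nrow(d), mean(d$E_mm), sum(d$E_mm)))
    }
    if (!file.exists(ev) && !file.exists(dl)) {
      say("nothing to report in ", parsed$outdir)
      status <- 1L
    }
  } else {
    stop("fieldET: unknown subcommand '", sub, "'", call. = FALSE)
  }
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
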