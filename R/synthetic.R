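#' Configuration of the synthetic field scene
#'
#' Describes the world the generators emulate: a maize-like field observed
#' by a daily cloud-free metre-scale NDVI product, an on-site flux tower
#' with an imposed energy-balance closure gap, and Great-Plains-style
#' summer meteorology. Defaults are the package's stated test world: a
#' 64 x 64 pixel grid at 3 m and a 150-day season.
#'
#' @param grid_shape Integer `(rows, cols)` of the scene.
#' @param pixel_size Pixel size (m).
#' @param season_start,season_end First and last simulated dates (one NDVI
#'   grid and 24 hourly records per day, inclusive).
#' @param sowing_doy,harvest_doy Day-of-year of sowing and harvest;
#'   `sowing_doy < harvest_doy`.
#' @param ndvi_base,ndvi_peak Off-season and peak NDVI
#'   (`0 <= base < peak <= 1`).
#' @param green_up_rate,senescence_rate Logistic rates (1/day) of green-up
#'   and senescence.
#' @param greenup_lag,senescence_lag Days from sowing to the green-up
#'   inflection and from harvest back to the senescence inflection.
#' @param n_patches Number of circular low-vigour heterogeneity patches.
#' @param patch_amplitude_drop Fractional reduction of the seasonal NDVI
#'   amplitude inside patches.
#' @param patch_radius Patch radius (pixels).
#' @param cloud_prob Probability that a day's net radiation is attenuated
#'   by cloud.
#' @param cloud_attenuation Fractional reduction of Rn on cloudy days.
#' @param closure_gap_fraction Fraction of the true latent heat flux
#'   removed from the measured LE (the closure gap); in `[0, 0.5]`.
#' @param noise_sd Gaussian noise added to measured LE (W/m2).
#' @param seed Integer RNG seed; identical configs give bit-identical
#'   output.
#' @param irrigation_events Data frame with columns `date`, `depth_mm`
#'   (may be empty).
#' @param rain_model List with `p_wet` (probability a day has rain),
#'   `depth_shape` and `depth_mean` (gamma daily depth, mm).
#' @param rn_peak Clear-sky solar-noon net radiation (W/m2).
#' @param sunrise_hour,sunset_hour Daylight window (local solar hours) of
#'   the half-sine Rn course.
#' @param ta_base,ta_seasonal_amp Annual mean and seasonal amplitude of
#'   daily mean air temperature (degC); seasonal peak near DOY 201.
#' @param ta_diurnal_amp Diurnal Ta amplitude (degC, max mid-afternoon).
#' @param ta_noise_sd Daily Ta anomaly s.d. (degC).
#' @param rh_mean,rh_diurnal_amp Mean relative humidity and its diurnal
#'   amplitude (fractions; RH moves in anti-phase with Ta).
#' @param rh_noise_sd Daily RH anomaly s.d. (fraction).
#' @param longitude Site longitude (degrees east).
#' @param tz_offset Timezone UTC offset (hours) of the local clock.
#' @param tower_pixel Integer `(row, col)` of the flux tower pixel;
#'   defaults to the grid centre.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(64L, 64L),
                             pixel_size = 3,
                             season_start = "2019-05-01",
                             season_end = "2019-09-27",
                             sowing_doy = 121L,
                             harvest_doy = 270L,
                             ndvi_base = 0.15,
                             ndvi_peak = 0.90,
                             green_up_rate = 0.12,
                             senescence_rate = 0.10,
                             greenup_lag = 45,
                             senescence_lag = 35,
                             n_patches = 3L,
                             patch_amplitude_drop = 0.3,
                             patch_radius = 6L,
                             cloud_prob = 0.3,
                             cloud_attenuation = 0.4,
                             closure_gap_fraction = 0.15,
                             noise_sd = 15,
                             seed = 42L,
                             irrigation_events = NULL,
                             rain_model = list(p_wet = 0.25,
                                               depth_shape = 1.2,
                                               depth_mean = 8),
                             rn_peak = 650,
                             sunrise_hour = 6,
                             sunset_hour = 18,
                             ta_base = 12,
                             ta_seasonal_amp = 12,
                             ta_diurnal_amp = 6,
                             ta_noise_sd = 1.5,
                             rh_mean = 0.65,
                             rh_diurnal_amp = 0.25,
                             rh_noise_sd = 0.05,
                             longitude = -96.47,
                             tz_offset = -6,
                             tower_pixel = NULL) {
  cfg <- as.list(environment())
  cfg$season_start <- as.Date(season_start)
  cfg$season_end <- as.Date(season_end)
  if (cfg$season_end < cfg$season_start) {
    stop("synthetic_config: season_end precedes season_start", call. = FALSE)
  }
  if (!(ndvi_base >= 0 && ndvi_base < ndvi_peak && ndvi_peak <= 1)) {
    stop("synthetic_config: need 0 <= ndvi_base < ndvi_peak <= 1",
         call. = FALSE)
  }
  if (sowing_doy >= harvest_doy) {
    stop("synthetic_config: sowing_doy must precede harvest_doy",
         call. = FALSE)
  }
  if (closure_gap_fraction < 0 || closure_gap_fraction > 0.5) {
    stop("synthetic_config: closure_gap_fraction must lie in [0, 0.5]",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("synthetic_config: noise_sd must be >= 0",
                         call. = FALSE)
  if (cloud_prob < 0 || cloud_prob > 1 ||
      cloud_attenuation < 0 || cloud_attenuation > 1) {
    stop("synthetic_config: cloud parameters must lie in [0, 1]",
         call. = FALSE)
  }
  if (length(grid_shape) != 2L || any(grid_shape < 1)) {
    stop("synthetic_config: grid_shape must be (rows, cols)", call. = FALSE)
  }
  cfg$grid_shape <- as.integer(grid_shape)
  cfg$seed <- as.integer(seed)
  if (is.null(tower_pixel)) {
    cfg$tower_pixel <- as.integer(ceiling(cfg$grid_shape / 2))
  } else {
    cfg$tower_pixel <- as.integer(tower_pixel)
  }
  if (any(cfg$tower_pixel < 1) || any(cfg$tower_pixel > cfg$grid_shape)) {
    stop("synthetic_config: tower_pixel outside the grid", call. = FALSE)
  }
  if (is.null(irrigation_events)) {
    cfg$irrigation_events <- data.frame(date = as.Date(character()),
                                        depth_mm = numeric())
  } else {
    cfg$irrigation_events <- data.frame(
      date = as.Date(irrigation_events$date),
      depth_mm = as.numeric(irrigation_events$depth_mm))
  }
  structure(cfg, class = "synthetic_config")
}

# Double-logistic seasonal NDVI course. `amplitude` is peak - base before
# any patch reduction; inflections at sowing+greenup_lag / harvest-senescence_lag.
double_logistic_ndvi <- function(doy, base, amplitude, cfg) {
  d_up <- cfg$sowing_doy + cfg$greenup_lag
  d_down <- cfg$harvest_doy - cfg$senescence_lag
  v <- base + amplitude *
    (stats::plogis(cfg$green_up_rate * (doy - d_up)) -
       stats::plogis(cfg$senescence_rate * (doy - d_down)))
  pmin(pmax(v, 0), 1)
}

day_of_year <- function(dates) as.POSIXlt(dates)$yday + 1L

#' Generate a daily NDVI stack with heterogeneity patches
#'
#' Every pixel follows a double-logistic seasonal NDVI curve; inside the
#' randomly placed circular patches the seasonal amplitude is reduced by
#' `patch_amplitude_drop`. One grid per day from `season_start` to
#' `season_end`.
#'
#' @param config A [synthetic_config()].
#' @return An [ndvi_stack()] with attributes `patch_mask` (logical matrix
#'   of patch membership) and `tower_pixel`.
#' @export
gen_ndvi_stack <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  rows <- config$grid_shape[1]
  cols <- config$grid_shape[2]
  r <- config$patch_radius
  patch <- matrix(FALSE, rows, cols)
  if (config$n_patches > 0) {
    if (2 * r + 1 > min(rows, cols) ||
        config$n_patches * pi * r^2 > 0.5 * rows * cols) {
      stop("gen_ndvi_stack: grid too small to place ", config$n_patches,
           " patches of radius ", r, call. = FALSE)
    }
    set.seed(config$seed)
    ri <- matrix(seq_len(rows), rows, cols)
    ci <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    for (k in seq_len(config$n_patches)) {
      cr <- sample(seq(r + 1L, rows - r), 1L)
      cc <- sample(seq(r + 1L, cols - r), 1L)
      patch <- patch | ((ri - cr)^2 + (ci - cc)^2 <= r^2)
    }
  }
  amplitude <- matrix(config$ndvi_peak - config$ndvi_base, rows, cols)
  amplitude[patch] <- amplitude[patch] * (1 - config$patch_amplitude_drop)
  dates <- seq(config$season_start, config$season_end, by = "day")
  doy <- day_of_year(dates)
  grids <- array(NA_real_, c(rows, cols, length(dates)))
  for (i in seq_along(dates)) {
    grids[, , i] <- double_logistic_ndvi(doy[i], config$ndvi_base,
                                         amplitude, config)
  }
  stk <- ndvi_stack(dates, grids,
                    list(x_origin = 0,
                         y_origin = rows * config$pixel_size,
                         pixel_size = config$pixel_size))
  attr(stk, "patch_mask") <- patch
  attr(stk, "tower_pixel") <- config$tower_pixel
  stk
}

#' Generate hourly synthetic meteorology
#'
#' Net radiation follows a clipped half-sine over the daylight window,
#' scaled on cloudy days by `1 - cloud_attenuation`; air temperature is a
#' seasonal plus diurnal sinusoid with a daily anomaly; relative humidity
#' moves in anti-phase with temperature; rain falls on random days with
#' gamma-distributed depths placed in one random hour.
#'
#' Per-day RNG draw order (seed `config$seed + 1`): cloud uniform, Ta
#' anomaly, RH anomaly, wet-day uniform, rain depth, rain hour.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `timestamp`, `Ta`, `RH`, `Rn`, `P`
#'   (one row per hour) and attribute `tz_offset`.
#' @export
gen_met_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  dates <- seq(config$season_start, config$season_end, by = "day")
  doy <- day_of_year(dates)
  n_days <- length(dates)
  cloudy <- logical(n_days)
  ta_anom <- rh_anom <- depth <- numeric(n_days)
  rain_hour <- integer(n_days)
  for (i in seq_len(n_days)) {
    cloudy[i] <- stats::runif(1) < config$cloud_prob
    ta_anom[i] <- stats::rnorm(1, 0, config$ta_noise_sd)
    rh_anom[i] <- stats::rnorm(1, 0, config$rh_noise_sd)
    wet <- stats::runif(1) < config$rain_model$p_wet
    depth[i] <- if (wet) {
      stats::rgamma(1, shape = config$rain_model$depth_shape,
                    scale = config$rain_model$depth_mean /
                      config$rain_model$depth_shape)
    } else 0
    rain_hour[i] <- sample.int(24L, 1L) - 1L
  }
  hours <- 0:23
  day_idx <- rep(seq_len(n_days), each = 24L)
  h <- rep(hours, n_days)
  timestamp <- as.POSIXct(rep(dates, each = 24L), tz = "UTC") + h * 3600
  dl <- config$sunset_hour - config$sunrise_hour
  rn_shape <- ifelse(h > config$sunrise_hour & h < config$sunset_hour,
                     sin(pi * (h - config$sunrise_hour) / dl), 0)
  rn <- pmax(rn_shape, 0) * config$rn_peak *
    ifelse(cloudy[day_idx], 1 - config$cloud_attenuation, 1)
  ta_mean <- config$ta_base +
    config$ta_seasonal_amp * sin(2 * pi * (doy[day_idx] - 110) / 365) +
    ta_anom[day_idx]
  diurnal <- sin(2 * pi * (h - 9) / 24)
  ta <- ta_mean + config$ta_diurnal_amp * diurnal
  rh <- pmin(pmax(config$rh_mean + rh_anom[day_idx] -
                    config$rh_diurnal_amp * diurnal, 0.05), 1)
  p <- ifelse(h == rain_hour[day_idx], depth[day_idx], 0)
  out <- data.frame(timestamp = timestamp, Ta = ta, RH = rh, Rn = rn, P = p)
  attr(out, "tz_offset") <- config$tz_offset
  out
}

#' Generate tower flux records and their truth
#'
#' Runs the PT-JPL model at the tower pixel to obtain the true latent heat
#' flux, then constructs the measured record: soil heat flux G from the
#' diurnal cosine model, sensible heat `H = Rn - G - LE_true` (so the
#' energy balance closes exactly on the truth, i.e. the whole imposed gap
#' sits in LE, matching the residual correction's assumption that H is
#' measured correctly), and
#' `LE_measured = LE_true * (1 - closure_gap_fraction) + N(0, noise_sd)`.
#'
#' @param config A [synthetic_config()].
#' @param ndvi_at_tower Data frame `date`, `ndvi`: the daily NDVI at the
#'   tower pixel; must cover every date of `met`.
#' @param met Hourly meteorology from [gen_met_series()].
#' @param params A [ptjpl_params()] object; its `topt` is replaced by the
#'   seasonal estimate, as in the analysis pipeline.
#' @return List with `records` (data frame `timestamp`, `Ta`, `RH`, `Rn`,
#'   `G`, `H`, `LE`, `P`) and `truth`, an object of class
#'   `synthetic_truth`: hourly true `le_s`, `le_c`, `le_i`, `le_total`,
#'   the imposed `gap_series`, and the `topt` / `f_apar_max` used.
#' @export
gen_tower_record <- function(config, ndvi_at_tower, met,
                             params = ptjpl_params()) {
  stopifnot(inherits(config, "synthetic_config"))
  met_dates <- unique(as.Date(met$timestamp))
  if (!all(met_dates %in% as.Date(ndvi_at_tower$date))) {
    stop("gen_tower_record: ndvi_at_tower must cover every met date",
         call. = FALSE)
  }
  params$topt <- estimate_topt(met, ndvi_at_tower, params)
  ndvi <- ndvi_at_tower$ndvi[match(as.Date(met$timestamp),
                                   as.Date(ndvi_at_tower$date))]
  veg <- vegetation_indices(ndvi, params)
  f_apar_max <- max(vegetation_indices(ndvi_at_tower$ndvi, params)$f_apar)
  md <- met_derivatives(met$Ta, met$RH)
  cons <- ptjpl_constraints(md, veg, met$Ta, met$RH, params, f_apar_max)
  rad <- radiation_partition(met$Rn, veg$lai, params)
  tsol <- solar_seconds(met$timestamp, config$longitude, config$tz_offset)
  g <- soil_heat_flux(rad$rn_s, tsol, params)
  fx <- compute_fluxes(md, cons, rad, g, params)
  h_flux <- met$Rn - g - fx$le_total
  set.seed(config$seed + 2L)
  noise <- stats::rnorm(length(met$Rn), 0, config$noise_sd)
  le_meas <- fx$le_total * (1 - config$closure_gap_fraction) + noise
  records <- data.frame(timestamp = met$timestamp,
                        Ta = met$Ta, RH = met$RH, Rn = met$Rn,
                        G = g, H = h_flux, LE = le_meas, P = met$P)
  attr(records, "tz_offset") <- config$tz_offset
  truth <- structure(list(
    timestamp = met$timestamp,
    le_s = fx$le_s, le_c = fx$le_c, le_i = fx$le_i,
    le_total = fx$le_total,
    gap_series = fx$le_total * config$closure_gap_fraction,
    topt = params$topt,
    f_apar_max = f_apar_max
  ), class = "synthetic_truth")
  list(records = records, truth = truth)
}

#' Insert missing values and negative daytime LE into tower records
#'
#' Emulates the imperfections of real eddy-covariance series: a fraction
#' of daytime records lose their LE entirely and a further fraction get a
#' spurious negative daytime LE (set to minus its magnitude).
#'
#' @param records Tower records (from [gen_tower_record()]).
#' @param gap_fraction Fraction of daytime records whose LE is set missing.
#' @param neg_fraction Fraction of daytime records whose LE is negated.
#' @param seed RNG seed for the positions.
#' @return `records` with attributes `gap_idx` and `neg_idx` (row indices).
#' @export
insert_gaps <- function(records, gap_fraction = 0.014,
                        neg_fraction = 0.025, seed = 1L) {
  if (gap_fraction < 0 || gap_fraction >= 0.5 ||
      neg_fraction < 0 || neg_fraction >= 0.5) {
    stop("insert_gaps: fractions must lie in [0, 0.5)", call. = FALSE)
  }
  day_idx <- which(daytime_mask(records))
  n_gap <- round(gap_fraction * length(day_idx))
  n_neg <- round(neg_fraction * length(day_idx))
  if (n_gap + n_neg > length(day_idx)) {
    stop("insert_gaps: fractions infeasible for series length",
         call. = FALSE)
  }
  set.seed(seed)
  gap_idx <- if (n_gap > 0) sort(sample(day_idx, n_gap)) else integer()
  rest <- setdiff(day_idx, gap_idx)
  neg_idx <- if (n_neg > 0) sort(sample(rest, n_neg)) else integer()
  records$LE[gap_idx] <- NA
  records$LE[neg_idx] <- -abs(records$LE[neg_idx])
  attr(records, "gap_idx") <- gap_idx
  attr(records, "neg_idx") <- neg_idx
  records
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper tying the generators together in a fixed order:
#' NDVI stack, meteorology, tower records with truth, and a rectangular
#' field boundary inset two pixels from the grid edge.
#'
#' @param config A [synthetic_config()].
#' @param params A [ptjpl_params()] object.
#' @return List with `stack`, `met`, `records`, `truth`, `boundary`,
#'   `config`.
#' @export
gen_synthetic_dataset <- function(config = synthetic_config(),
                                  params = ptjpl_params()) {
  stack <- gen_ndvi_stack(config)
  met <- gen_met_series(config)
  tp <- config$tower_pixel
  ndvi_at_tower <- data.frame(date = stack$dates,
                              ndvi = stack$grids[tp[1], tp[2], ])
  tower <- gen_tower_record(config, ndvi_at_tower, met, params)
  px <- config$pixel_size
  rows <- config$grid_shape[1]
  cols <- config$grid_shape[2]
  m <- 2 * px
  boundary <- field_boundary(rbind(c(m, m),
                                   c(cols * px - m, m),
                                   c(cols * px - m, rows * px - m),
                                   c(m, rows * px - m)),
                             site_id = "synthetic-field")
  list(stack = stack, met = met, records = tower$records,
       truth = tower$truth, boundary = boundary, config = config)
}
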