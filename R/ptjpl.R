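#' Psychrometric derivatives of air temperature and humidity
#'
#' Saturation vapour pressure (Magnus/FAO-56 form), actual vapour pressure,
#' vapour pressure deficit and the slope of the saturation curve.
#'
#' @param ta Air temperature (degC); must lie in (-40, 60).
#' @param rh Relative humidity as a fraction in `[0, 1]`.
#' @return A list with elements `e_sat`, `e_a`, `vpd` (kPa) and `delta`
#'   (kPa/degC), each the shape of the inputs.
#' @export
#' @examples
#' met_derivatives(25, 0.5)$vpd  # ~1.58 kPa
met_derivatives <- function(ta, rh) {
  if (any(!is.finite(ta)) || any(ta <= -40 | ta >= 60)) {
    stop("met_derivatives: ta must be finite and within (-40, 60) degC",
         call. = FALSE)
  }
  if (any(!is.finite(rh)) || any(rh < 0 | rh > 1)) {
    stop("met_derivatives: rh must be a fraction in [0, 1]", call. = FALSE)
  }
  e_sat <- 0.6108 * exp(17.27 * ta / (ta + 237.3))
  e_a <- rh * e_sat
  list(e_sat = e_sat,
       e_a = e_a,
       vpd = e_sat - e_a,
       delta = 4098 * e_sat / (ta + 237.3)^2)
}

#' NDVI-derived vegetation indices
#'
#' Maps NDVI to the soil-adjusted vegetation index (linear proxy), fractions
#' of absorbed and intercepted PAR, canopy cover and leaf area index
#' (Beer-Lambert inversion). All fractions are clipped to `[0, 1]`; canopy
#' cover is capped at 0.98 before the logarithm so LAI stays finite.
#'
#' @param ndvi NDVI in `[-1, 1]`; vector, matrix or array.
#' @param params A [ptjpl_params()] object.
#' @return List with elements `savi`, `f_apar`, `f_ipar`, `f_c`, `lai`,
#'   each the shape of `ndvi`.
#' @export
#' @examples
#' vegetation_indices(0.8, ptjpl_params())$lai  # ~2.77
vegetation_indices <- function(ndvi, params = ptjpl_params()) {
  if (any(!is.na(ndvi) & (ndvi < -1 | ndvi > 1))) {
    stop("vegetation_indices: ndvi must lie in [-1, 1]", call. = FALSE)
  }
  savi <- params$savi_slope * ndvi + params$savi_offset
  f_apar <- clip01(params$fapar_slope * savi + params$fapar_offset)
  f_ipar <- clip01(params$fipar_slope * ndvi + params$fipar_offset)
  f_c <- f_ipar
  lai <- -log(1 - pmin(f_c, 0.98)) / params$k_par
  list(savi = savi, f_apar = f_apar, f_ipar = f_ipar, f_c = f_c, lai = lai)
}

#' Biophysical constraints of the PT-JPL model
#'
#' The five multiplicative reduction factors applied to Priestley-Taylor
#' potential evaporation: surface wetness `f_wet = RH^4`, green canopy
#' fraction `f_g = f_APAR/f_IPAR`, plant temperature response
#' `f_T = exp(-((Ta - Topt)/Topt)^2)`, plant moisture
#' `f_M = f_APAR/f_APAR_max` and soil moisture `f_SM = RH^(VPD/beta)`
#' (1 when VPD <= 0). All are clipped to `[0, 1]`.
#'
#' @param md Output of [met_derivatives()] (needs `vpd`).
#' @param veg Output of [vegetation_indices()] (needs `f_apar`, `f_ipar`).
#' @param ta Air temperature (degC), same shape as `md` inputs.
#' @param rh Relative humidity fraction.
#' @param params A [ptjpl_params()] object; `topt` must be > 0.
#' @param f_apar_max Seasonal maximum fAPAR (scalar or the shape of
#'   `veg$f_apar`); must be > 0.
#' @return List with elements `f_wet`, `f_g`, `f_t`, `f_m`, `f_sm`.
#' @export
ptjpl_constraints <- function(md, veg, ta, rh, params = ptjpl_params(),
                              f_apar_max = 1) {
  if (params$topt <= 0) {
    stop("ptjpl_constraints: topt must be > 0 degC", call. = FALSE)
  }
  if (any(f_apar_max <= 0)) {
    stop("ptjpl_constraints: f_apar_max must be > 0", call. = FALSE)
  }
  f_wet <- clip01(rh^4)
  f_g <- ifelse(veg$f_ipar > 0, clip01(veg$f_apar / veg$f_ipar), 0)
  f_t <- clip01(exp(-((ta - params$topt) / params$topt)^2))
  f_m <- clip01(veg$f_apar / f_apar_max)
  f_sm <- ifelse(md$vpd <= 0, 1, clip01(rh^(md$vpd / params$beta)))
  list(f_wet = f_wet, f_g = f_g, f_t = f_t, f_m = f_m, f_sm = f_sm)
}

#' Estimate the temperature optimum from a season of forcing
#'
#' Returns the air temperature of the daytime hour that maximizes
#' `f_APAR * Rn * Ta / VPD` over the record, the usual proxy for peak
#' canopy activity. Falls back to 25 degC when no daytime hour with
#' positive VPD (and positive Ta) exists.
#'
#' @param records Hourly meteorology data frame with columns `timestamp`,
#'   `Ta`, `RH`, `Rn` (see [read_met_csv()]).
#' @param ndvi_daily Data frame with columns `date` and `ndvi`: the NDVI
#'   trajectory at the location of interest, one row per day.
#' @param params A [ptjpl_params()] object.
#' @return Temperature optimum (degC).
#' @export
estimate_topt <- function(records, ndvi_daily, params = ptjpl_params()) {
  if (nrow(records) == 0L) {
    stop("estimate_topt: empty record set", call. = FALSE)
  }
  ndvi <- ndvi_daily$ndvi[match(as.Date(records$timestamp),
                                as.Date(ndvi_daily$date))]
  md <- met_derivatives(records$Ta, records$RH)
  veg <- vegetation_indices(ndvi, params)
  ok <- !is.na(ndvi) & !is.na(records$Rn) & records$Rn > 0 &
    md$vpd > 1e-9 & records$Ta > 0
  if (!any(ok)) return(25)
  score <- veg$f_apar[ok] * records$Rn[ok] * records$Ta[ok] / md$vpd[ok]
  records$Ta[ok][which.max(score)]
}

#' Partition net radiation between canopy and soil
#'
#' Beer-Lambert attenuation of net radiation through the canopy:
#' `Rn_s = Rn * exp(-k_rn * LAI)`, `Rn_c = Rn - Rn_s`.
#'
#' @param rn Net radiation (W/m2); scalar or array.
#' @param lai Leaf area index, same shape as `rn` (or scalar).
#' @param params A [ptjpl_params()] object.
#' @return List with `rn_s` (soil) and `rn_c` (canopy) in W/m2.
#' @export
radiation_partition <- function(rn, lai, params = ptjpl_params()) {
  rn_s <- rn * exp(-params$k_rn * lai)
  list(rn_s = rn_s, rn_c = rn - rn_s)
}

#' Diurnal soil heat flux
#'
#' Cosine model of the soil heat flux as a fraction of soil net radiation,
#' `G = A * cos(2*pi*(t + 10800)/B) * Rn_s`, peaking three hours before
#' solar noon. `G` is floored at zero where `Rn_s > 0` and zero where
#' `Rn_s <= 0` (the model is daytime-only).
#'
#' @param rn_s Soil net radiation (W/m2).
#' @param t_solar Seconds relative to local solar noon, in
#'   `[-43200, 43200]`; scalar or the shape of `rn_s`.
#' @param params A [ptjpl_params()] object (`g_amplitude`, `g_period`).
#' @return Soil heat flux G (W/m2), same shape as `rn_s`.
#' @export
#' @examples
#' soil_heat_flux(400, -10800)  # peak: 0.31 * 400
soil_heat_flux <- function(rn_s, t_solar, params = ptjpl_params()) {
  if (any(abs(t_solar) > 43200)) {
    stop("soil_heat_flux: |t_solar| must be <= 43200 s", call. = FALSE)
  }
  g <- params$g_amplitude *
    cos(2 * pi * (t_solar + 10800) / params$g_period) * rn_s
  ifelse(rn_s > 0, pmax(g, 0), 0)
}

#' Seconds from local solar noon
#'
#' Converts clock timestamps (local standard time) to seconds relative to
#' local solar noon using the longitude correction against the timezone
#' meridian (4 minutes per degree). The equation of time is ignored
#' (<= ~15 min error).
#'
#' @param timestamp POSIXct timestamps interpreted as local standard time.
#' @param longitude Site longitude (degrees east).
#' @param tz_offset Timezone UTC offset in hours (e.g. -6 for CST).
#' @return Seconds relative to solar noon (negative = morning).
#' @export
solar_seconds <- function(timestamp, longitude, tz_offset) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  clock <- lt$hour * 3600 + lt$min * 60 + lt$sec
  meridian <- 15 * tz_offset
  t <- clock - 12 * 3600 + (longitude - meridian) * 240
  # wrap into [-43200, 43200]
  ((t + 43200) %% 86400) - 43200
}

#' Three-component PT-JPL latent heat flux
#'
#' Partitions Priestley-Taylor potential evaporation into soil, canopy and
#' interception latent heat fluxes using the biophysical constraints. With
#' `PT = alpha * delta / (delta + gamma)`:
#' \itemize{
#'   \item `LE_c = (1 - f_wet) * f_g * f_t * f_m * PT * Rn_c`
#'   \item `LE_s = (f_wet + f_sm * (1 - f_wet)) * PT * max(Rn_s - G, 0)`
#'   \item `LE_i = f_wet * PT * Rn_c`
#' }
#' Each component is floored at zero (daytime condensation excluded) and
#' `LE_total` is their exact sum.
#'
#' @param md Output of [met_derivatives()] (needs `delta`).
#' @param cons Output of [ptjpl_constraints()].
#' @param rad Output of [radiation_partition()].
#' @param g Soil heat flux (W/m2), from [soil_heat_flux()].
#' @param params A [ptjpl_params()] object.
#' @return List of class `flux_components`: `le_s`, `le_c`, `le_i`,
#'   `le_total` plus diagnostics `rn_s`, `rn_c`, `g` (W/m2), each the
#'   common shape of the inputs.
#' @export
compute_fluxes <- function(md, cons, rad, g, params = ptjpl_params()) {
  pt <- params$alpha * md$delta / (md$delta + params$gamma)
  le_c <- pmax((1 - cons$f_wet) * cons$f_g * cons$f_t * cons$f_m *
                 pt * rad$rn_c, 0)
  le_s <- pmax((cons$f_wet + cons$f_sm * (1 - cons$f_wet)) *
                 pt * pmax(rad$rn_s - g, 0), 0)
  le_i <- pmax(cons$f_wet * pt * rad$rn_c, 0)
  structure(list(le_s = le_s, le_c = le_c, le_i = le_i,
                 le_total = le_s + le_c + le_i,
                 rn_s = rad$rn_s, rn_c = rad$rn_c, g = g),
            class = "flux_components")
}

#' Per-pixel seasonal maximum fAPAR
#'
#' @param stack An [ndvi_stack()].
#' @param params A [ptjpl_params()] object.
#' @return Matrix of the per-pixel maximum fAPAR over the stack's dates.
#' @export
fapar_max_grid <- function(stack, params = ptjpl_params()) {
  f <- vegetation_indices(stack$grids, params)$f_apar
  apply(f, c(1, 2), max)
}

#' Run the PT-JPL model over one day's scene
#'
#' Applies the model to every pixel of the daily NDVI grid for every
#' daytime hour (Rn > 0) of that date, holding NDVI constant through the
#' day and treating the tower meteorology as spatially uniform.
#'
#' @param stack An [ndvi_stack()].
#' @param date The date to run (coerced with `as.Date`); must be in the
#'   stack.
#' @param records Hourly meteorology covering that date (columns
#'   `timestamp`, `Ta`, `RH`, `Rn`).
#' @param params A [ptjpl_params()] object (with `topt` already set).
#' @param f_apar_max Matrix from [fapar_max_grid()] (or scalar).
#' @param longitude,tz_offset Passed to [solar_seconds()] for the soil
#'   heat flux phase.
#' @return List with `date`, `hours` (POSIXct of the daytime hours) and
#'   `fluxes`, a list per hour of `flux_components` whose elements are
#'   matrices the shape of the grid.
#' @export
run_scene <- function(stack, date, records, params = ptjpl_params(),
                      f_apar_max = 1, longitude = 0, tz_offset = 0) {
  date <- as.Date(date)
  i <- match(date, stack$dates)
  if (is.na(i)) {
    stop("run_scene: date ", format(date), " not present in the NDVI stack",
         call. = FALSE)
  }
  grid <- stack$grids[, , i]
  day <- records[as.Date(records$timestamp) == date, , drop = FALSE]
  day <- day[!is.na(day$Rn) & day$Rn > 0, , drop = FALSE]
  if (nrow(day) == 0L) {
    stop("run_scene: no daytime hours on ", format(date), call. = FALSE)
  }
  veg <- vegetation_indices(grid, params)
  tsol <- solar_seconds(day$timestamp, longitude, tz_offset)
  fluxes <- vector("list", nrow(day))
  for (h in seq_len(nrow(day))) {
    md <- met_derivatives(day$Ta[h], day$RH[h])
    cons <- ptjpl_constraints(md, veg, day$Ta[h], day$RH[h], params,
                              f_apar_max)
    rad <- radiation_partition(day$Rn[h], veg$lai, params)
    g <- soil_heat_flux(rad$rn_s, tsol[h], params)
    fluxes[[h]] <- compute_fluxes(md, cons, rad, g, params)
  }
  list(date = date, hours = day$timestamp, fluxes = fluxes)
}
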