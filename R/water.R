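#' Convert latent heat flux to water depth
#'
#' `E (mm/h) = LE (W/m2) * 3600 / lambda_v` with the latent heat of
#' vaporization lambda_v (approx. 2260 kJ/kg).
#'
#' @param le Latent heat flux (W/m2); any numeric shape.
#' @param lambda_v Latent heat of vaporization (J/kg, > 0).
#' @return Evaporation rate (mm/h), same shape as `le`.
#' @export
#' @examples
#' flux_to_depth(226)  # 0.36 mm/h
flux_to_depth <- function(le, lambda_v = 2.26e6) {
  if (!is.numeric(lambda_v) || length(lambda_v) != 1L || lambda_v <= 0) {
    stop("flux_to_depth: lambda_v must be a single positive number",
         call. = FALSE)
  }
  le * 3600 / lambda_v
}

#' Convert water depth rate back to latent heat flux
#'
#' Exact inverse of [flux_to_depth()].
#'
#' @param e_mmh Evaporation rate (mm/h).
#' @param lambda_v Latent heat of vaporization (J/kg, > 0).
#' @return Latent heat flux (W/m2).
#' @export
depth_to_flux <- function(e_mmh, lambda_v = 2.26e6) {
  if (!is.numeric(lambda_v) || length(lambda_v) != 1L || lambda_v <= 0) {
    stop("depth_to_flux: lambda_v must be a single positive number",
         call. = FALSE)
  }
  e_mmh * lambda_v / 3600
}

#' Aggregate hourly evaporation to daily depths
#'
#' Sums hourly rates (mm/h) over the daytime hours of each date; nighttime
#' contributes nothing (the model is daytime-only). Dates with no daytime
#' hours get `NA`.
#'
#' @param e_mmh Hourly evaporation rates (mm/h).
#' @param timestamps POSIXct timestamps, same length.
#' @param daytime Logical daytime mask, same length (see [daytime_mask()]).
#' @return Data frame with columns `date` and `E_mm` (mm/day), one row per
#'   calendar day present in `timestamps`.
#' @export
aggregate_daily <- function(e_mmh, timestamps, daytime) {
  stopifnot(length(e_mmh) == length(timestamps),
            length(daytime) == length(timestamps))
  dates <- as.Date(timestamps)
  all_days <- sort(unique(dates))
  contrib <- ifelse(daytime, e_mmh, 0)
  sums <- tapply(contrib, dates, sum)
  has_day <- tapply(daytime, dates, any)
  out <- data.frame(date = all_days,
                    E_mm = as.numeric(sums[format(all_days)]))
  out$E_mm[!as.logical(has_day[format(all_days)])] <- NA
  out
}

#' Zonal statistics of a raster inside a field boundary
#'
#' Statistics over the pixels whose centers fall inside the polygon
#' (pixel-center containment: edge pixels whose centers are outside are
#' excluded).
#'
#' @param grid Numeric matrix.
#' @param geotransform Geotransform list (see [ndvi_stack()]).
#' @param boundary A [field_boundary()].
#' @param bin_width Histogram bin width (same units as the raster);
#'   ignored when `breaks` is given.
#' @param breaks Optional explicit histogram bin edges.
#' @return List with `mean`, `std` (sample s.d.), `histogram` (list
#'   `breaks`, `counts`), `n_pixels` and `mask` (logical matrix of the
#'   interior pixels).
#' @export
zonal_mean <- function(grid, geotransform, boundary, bin_width = 0.05,
                       breaks = NULL) {
  ctr <- pixel_centers(nrow(grid), ncol(grid), geotransform)
  inside <- matrix(point_in_polygon(as.vector(ctr$x), as.vector(ctr$y),
                                    boundary),
                   nrow(grid), ncol(grid))
  vals <- grid[inside]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    stop("zonal_mean: no pixel centers inside the boundary", call. = FALSE)
  }
  if (is.null(breaks)) {
    lo <- floor(min(vals) / bin_width) * bin_width
    hi <- ceiling(max(vals) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    breaks <- seq(lo, hi, by = bin_width)
    if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  }
  counts <- graphics::hist(vals, breaks = breaks, plot = FALSE)$counts
  list(mean = mean(vals),
       std = if (length(vals) > 1L) stats::sd(vals) else 0,
       histogram = list(breaks = breaks, counts = counts),
       n_pixels = length(vals),
       mask = inside)
}

# Least-squares polynomial value at `at` from points (t, y); used by the
# Savitzky-Golay filter for both interior and truncated edge windows.
polyfit_value <- function(t, y, order, at) {
  x <- t - at
  X <- outer(x, 0:order, `^`)
  qr.solve(X, y)[1]
}

#' Savitzky-Golay smoothing of a daily series
#'
#' Least-squares local polynomial smoothing: for each sample, a polynomial
#' of degree `polyorder` is fitted over a centred window of `window` days
#' and evaluated at the sample. At the series edges the window is
#' truncated to the available samples (still >= `polyorder + 1` points),
#' avoiding any extrapolation. Polynomials of degree <= `polyorder` are
#' reproduced exactly.
#'
#' @param x Numeric series (may contain `NA`, which are excluded from the
#'   fits; a sample with fewer than `polyorder + 1` valid neighbours stays
#'   `NA`).
#' @param window Odd window length, `> polyorder`.
#' @param polyorder Polynomial degree (>= 0).
#' @return Smoothed series, same length as `x`.
#' @export
smooth_series <- function(x, window = 15, polyorder = 3) {
  if (window %% 2 != 1 || window <= polyorder || polyorder < 0) {
    stop("smooth_series: need odd window > polyorder >= 0", call. = FALSE)
  }
  n <- length(x)
  if (n < window) {
    stop("smooth_series: series shorter than the window", call. = FALSE)
  }
  half <- (window - 1L) %/% 2L
  out <- rep(NA_real_, n)
  t <- seq_len(n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - half):min(n, i + half)
    ok <- idx[!is.na(x[idx])]
    if (length(ok) >= polyorder + 1L) {
      out[i] <- polyfit_value(t[ok], x[ok], polyorder, i)
    }
  }
  out
}

#' Cumulative evaporation versus water supply
#'
#' Running sums of daily evaporation and daily precipitation (plus
#' irrigation when requested) over the growing season.
#'
#' @param daily Data frame with columns `date`, `E_mm`, `precip_mm` and
#'   optionally `irrigation_mm`.
#' @param season Length-2 vector of sowing and harvest dates (inclusive).
#' @param include_irrigation Add irrigation depths into the cumulative
#'   water supply curve.
#' @return Data frame `date`, `cum_E`, `cum_P` (mm), restricted to the
#'   season; both columns are non-decreasing.
#' @export
cumulative_compare <- function(daily, season,
                               include_irrigation = TRUE) {
  season <- as.Date(season)
  d <- daily[daily$date >= season[1] & daily$date <= season[2], ,
             drop = FALSE]
  d <- d[order(d$date), , drop = FALSE]
  e <- d$E_mm
  e[is.na(e)] <- 0
  p <- d$precip_mm
  p[is.na(p)] <- 0
  if (include_irrigation && !is.null(d$irrigation_mm)) {
    irr <- d$irrigation_mm
    irr[is.na(irr)] <- 0
    p <- p + irr
  }
  data.frame(date = d$date, cum_E = cumsum(e), cum_P = cumsum(p))
}

#' Per-pixel cumulative evaporation map
#'
#' @param daily_grids 3-D array `[rows, cols, days]` of daily evaporation
#'   (mm/day).
#' @param dates Dates of the third dimension.
#' @param season Length-2 vector of sowing and harvest dates (inclusive).
#' @return Matrix of cumulative evaporation (mm) over the season.
#' @export
cumulative_e_map <- function(daily_grids, dates, season) {
  if (length(dim(daily_grids)) != 3L ||
      dim(daily_grids)[3] != length(dates)) {
    stop("cumulative_e_map: grids and dates are misaligned", call. = FALSE)
  }
  season <- as.Date(season)
  sel <- which(as.Date(dates) >= season[1] & as.Date(dates) <= season[2])
  if (length(sel) == 0L) {
    stop("cumulative_e_map: no dates inside the season", call. = FALSE)
  }
  apply(daily_grids[, , sel, drop = FALSE], c(1, 2),
        function(v) sum(v, na.rm = TRUE))
}

#' Flag underperforming pixels of a field
#'
#' Marks pixels inside the boundary whose value falls below
#' `zonal mean - k * zonal s.d.` — typically applied to a cumulative
#' evaporation map to locate low-water-use areas. With zero zonal spread
#' nothing is flagged.
#'
#' @param grid Numeric matrix (e.g. from [cumulative_e_map()]).
#' @param geotransform Geotransform list.
#' @param boundary A [field_boundary()].
#' @param k Standard-deviation multiplier (default 1.5).
#' @return Logical matrix; `TRUE` only for flagged interior pixels.
#' @export
underperformance_mask <- function(grid, geotransform, boundary, k = 1.5) {
  z <- zonal_mean(grid, geotransform, boundary)
  flag <- matrix(FALSE, nrow(grid), ncol(grid))
  if (z$std > 0) {
    thr <- z$mean - k * z$std
    flag <- z$mask & !is.na(grid) & grid < thr
  }
  flag
}
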