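#' Read an AmeriFlux-style hourly tower CSV
#'
#' Expected columns: `TIMESTAMP_START` (YYYYMMDDHHMM, local standard time),
#' `TA` (degC), `RH`, `NETRAD`, `G`, `H`, `LE` (W/m2) and `P` (mm). The
#' -9999 sentinel is mapped to `NA` and RH is normalized to a fraction.
#'
#' @param path Path to the CSV file.
#' @param tz_offset Timezone UTC offset in hours of the timestamps (local
#'   standard time); stored as an attribute because solar-time computations
#'   need it.
#' @param rh_unit `"percent"` (the AmeriFlux convention), `"fraction"`, or
#'   `"auto"` (percent assumed when values exceed 1.5).
#' @return Data frame with columns `timestamp` (POSIXct), `Ta`, `RH`
#'   (fraction), `Rn`, `G`, `H`, `LE`, `P`, with attribute `tz_offset`.
#'   Timestamps are checked to be strictly increasing and hourly.
#' @export
read_met_csv <- function(path, tz_offset = 0,
                         rh_unit = c("percent", "fraction", "auto")) {
  rh_unit <- match.arg(rh_unit)
  if (!file.exists(path)) {
    stop("read_met_csv: file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE)
  required <- c("TIMESTAMP_START", "TA", "RH", "NETRAD", "G", "H", "LE", "P")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("read_met_csv: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ts <- as.POSIXct(sprintf("%012.0f", as.numeric(raw$TIMESTAMP_START)),
                   format = "%Y%m%d%H%M", tz = "UTC")
  if (anyNA(ts)) {
    stop("read_met_csv: unparseable TIMESTAMP_START values", call. = FALSE)
  }
  dt <- diff(as.numeric(ts))
  if (any(dt <= 0)) {
    stop("read_met_csv: timestamps must be strictly increasing",
         call. = FALSE)
  }
  if (any(dt != 3600)) {
    stop("read_met_csv: timestamps must be hourly", call. = FALSE)
  }
  num <- function(x) {
    x <- as.numeric(x)
    x[x == -9999] <- NA
    x
  }
  rh <- num(raw$RH)
  if (rh_unit == "auto") {
    rh_unit <- if (max(rh, na.rm = TRUE) > 1.5) "percent" else "fraction"
  }
  if (rh_unit == "percent") rh <- rh / 100
  if (any(!is.na(rh) & (rh < 0 | rh > 1))) {
    stop("read_met_csv: RH outside [0, 1] after unit normalization",
         call. = FALSE)
  }
  out <- data.frame(timestamp = ts,
                    Ta = num(raw$TA), RH = rh, Rn = num(raw$NETRAD),
                    G = num(raw$G), H = num(raw$H), LE = num(raw$LE),
                    P = num(raw$P))
  attr(out, "tz_offset") <- tz_offset
  out
}

#' Write hourly tower records as AmeriFlux-style CSV
#'
#' Inverse of [read_met_csv()]: RH written in percent, `NA` as -9999,
#' numbers with full precision so values round-trip.
#'
#' @param records Data frame as returned by [read_met_csv()] or
#'   [gen_tower_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_met_csv <- function(records, path) {
  fmt <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "-9999"
    out
  }
  df <- data.frame(
    TIMESTAMP_START = format(records$timestamp, "%Y%m%d%H%M", tz = "UTC"),
    TA = fmt(records$Ta),
    RH = fmt(records$RH * 100),
    NETRAD = fmt(records$Rn),
    G = fmt(records$G),
    H = fmt(records$H),
    LE = fmt(records$LE),
    P = fmt(records$P)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Daytime mask
#'
#' A record counts as daytime when net radiation is positive; missing Rn
#' is treated as nighttime.
#'
#' @param records Hourly records with an `Rn` column.
#' @return Logical vector, one element per record.
#' @export
daytime_mask <- function(records) {
  !is.na(records$Rn) & records$Rn > 0
}

#' Linear gap filling of an hourly series
#'
#' Interior missing values are replaced by time-linear interpolation
#' between the nearest valid neighbours; leading and trailing gaps are
#' filled by nearest-value extension (no extrapolation).
#'
#' @param records Hourly records data frame.
#' @param field Column name to fill (e.g. `"LE"`).
#' @return `records` with the field filled; the number of filled values is
#'   attached as attribute `n_filled`.
#' @export
gap_fill_linear <- function(records, field) {
  x <- records[[field]]
  if (is.null(x)) stop("gap_fill_linear: no column '", field, "'",
                       call. = FALSE)
  miss <- is.na(x)
  if (all(miss)) {
    stop("gap_fill_linear: all values of '", field, "' are missing",
         call. = FALSE)
  }
  if (any(miss)) {
    if (sum(!miss) == 1L) {
      x[miss] <- x[!miss]  # single anchor: nearest-value extension
    } else {
      t <- as.numeric(records$timestamp)
      x[miss] <- stats::approx(t[!miss], x[!miss], xout = t[miss],
                               method = "linear", rule = 2)$y
    }
    records[[field]] <- x
  }
  attr(records, "n_filled") <- sum(miss)
  records
}

#' Screen physically implausible negative daytime latent heat
#'
#' Negative daytime LE would imply daytime condensation; such values are
#' set to missing and refilled with [gap_fill_linear()]. Nighttime values
#' are untouched. In the rare case that the refill itself lands negative
#' (both interpolation anchors being negative nighttime values), the
#' artifact is floored at zero so screening can never leave a negative
#' daytime LE behind.
#'
#' @param records Hourly records data frame with `Rn` and `LE`.
#' @return `records` with screened-and-refilled LE; counts are attached
#'   as attributes `n_screened` and `n_floored`.
#' @export
screen_negative_daytime_le <- function(records) {
  day <- daytime_mask(records)
  bad <- day & !is.na(records$LE) & records$LE < 0
  if (any(bad)) {
    records$LE[bad] <- NA
    records <- gap_fill_linear(records, "LE")
  }
  still <- day & !is.na(records$LE) & records$LE < 0
  records$LE[still] <- 0
  attr(records, "n_screened") <- sum(bad)
  attr(records, "n_floored") <- sum(still)
  records
}

#' Energy-balance residual closure correction
#'
#' Eddy-covariance towers typically under-measure the turbulent fluxes;
#' closing the balance as a residual, `LE = Rn - G - H`, attributes the
#' whole gap to the latent heat flux (assuming H is measured correctly).
#'
#' @param records Hourly records with `Rn`, `G`, `H`.
#' @return Numeric vector of corrected LE (W/m2); `NA` where any input is
#'   missing. The measured LE column in `records` is left untouched for
#'   diagnostics.
#' @export
closure_correct <- function(records) {
  records$Rn - records$G - records$H
}
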