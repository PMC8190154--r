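#' Pair modeled and measured hourly series
#'
#' Joins the modeled and closure-corrected tower series on timestamp and
#' keeps only daytime, in-season pairs where both values are present.
#'
#' @param model Data frame with columns `timestamp` and `E` (modeled,
#'   mm/h or W/m2 — any common unit).
#' @param tower Data frame with columns `timestamp` and `E` (measured,
#'   same unit).
#' @param season Optional length-2 vector of sowing/harvest dates
#'   (inclusive); `NULL` keeps all dates.
#' @param daytime Optional data frame `timestamp`, `mask` restricting the
#'   pairing to daytime hours; `NULL` keeps all hours.
#' @return Data frame with columns `timestamp`, `x` (measured), `y`
#'   (modeled).
#' @export
pair_series <- function(model, tower, season = NULL, daytime = NULL) {
  pairs <- merge(data.frame(timestamp = model$timestamp, y = model$E),
                 data.frame(timestamp = tower$timestamp, x = tower$E),
                 by = "timestamp")
  if (!is.null(season)) {
    season <- as.Date(season)
    d <- as.Date(pairs$timestamp)
    pairs <- pairs[d >= season[1] & d <= season[2], , drop = FALSE]
  }
  if (!is.null(daytime)) {
    dm <- merge(pairs["timestamp"],
                data.frame(timestamp = daytime$timestamp,
                           mask = daytime$mask),
                by = "timestamp", all.x = TRUE)
    keep <- !is.na(dm$mask) & dm$mask
    pairs <- pairs[keep, , drop = FALSE]
  }
  pairs <- pairs[!is.na(pairs$x) & !is.na(pairs$y), , drop = FALSE]
  if (nrow(pairs) == 0L) {
    stop("pair_series: no overlapping valid samples", call. = FALSE)
  }
  pairs[, c("timestamp", "x", "y")]
}

#' Evaluation statistics of modeled versus measured fluxes
#'
#' Computes the coefficient of determination
#' `r2 = (cov(x, y) / (sd(x) * sd(y)))^2`, the mean bias
#' `mean(y - x)`, the mean absolute error `mean(|y - x|)`, and the bias
#' normalized by the range of the measured values
#' (`100 * |bias| / (max(x) - min(x))`, in percent). Covariance and
#' standard deviations use the population (1/n) convention; r2 is then
#' the squared Pearson correlation under either convention.
#'
#' @param pairs Data frame with columns `x` (measured) and `y` (modeled),
#'   e.g. from [pair_series()].
#' @return Object of class `eval_stats`: list with `r2`, `bias`,
#'   `bias_norm`, `mae`, `n`. With zero variance in either series `r2` is
#'   `NA` with an explanatory attribute `r2_reason`.
#' @export
#' @examples
#' compute_stats(data.frame(x = c(1, 2, 3), y = c(2, 2, 5)))
compute_stats <- function(pairs) {
  x <- pairs$x
  y <- pairs$y
  n <- length(x)
  if (n < 2L) stop("compute_stats: need at least 2 pairs", call. = FALSE)
  bias <- mean(y - x)
  mae <- mean(abs(y - x))
  sx2 <- mean(x^2) - mean(x)^2
  sy2 <- mean(y^2) - mean(y)^2
  r2 <- NA_real_
  r2_reason <- NULL
  if (sx2 > 0 && sy2 > 0) {
    covxy <- mean(x * y) - mean(x) * mean(y)
    r2 <- min((covxy / sqrt(sx2 * sy2))^2, 1)
  } else {
    r2_reason <- "zero variance in one of the series"
  }
  rng <- max(x) - min(x)
  bias_norm <- if (rng > 0) 100 * abs(bias) / rng else NA_real_
  out <- structure(list(r2 = r2, bias = bias, bias_norm = bias_norm,
                        mae = mae, n = n),
                   class = "eval_stats")
  if (!is.null(r2_reason)) attr(out, "r2_reason") <- r2_reason
  out
}

#' @export
print.eval_stats <- function(x, ...) {
  cat(sprintf("Evaluation over n = %d pairs\n", x$n))
  cat(sprintf("  r2   = %s\n",
              if (is.na(x$r2)) paste0("NA (", attr(x, "r2_reason"), ")")
              else sprintf("%.4f", x$r2)))
  cat(sprintf("  bias = %.4g (%.2f%% of measured range)\n",
              x$bias, x$bias_norm))
  cat(sprintf("  MAE  = %.4g\n", x$mae))
  invisible(x)
}
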