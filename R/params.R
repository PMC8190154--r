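#' PT-JPL model parameters
#'
#' Bundle of the constants driving the three-component Priestley-Taylor
#' PT-JPL latent heat flux model. Every constant the model uses is exposed
#' here so that under-determined choices (vegetation index mappings,
#' extinction coefficients, the temperature optimum) are explicit,
#' overridable experiment parameters rather than magic numbers.
#'
#' @param alpha Priestley-Taylor coefficient (dimensionless, > 0).
#' @param beta Soil-moisture sensitivity scale for `f_SM = RH^(VPD/beta)`
#'   (kPa, > 0).
#' @param gamma Psychrometric constant (kPa/degC). Fixed by default because
#'   the forcing carries no surface pressure; override for elevation.
#' @param k_rn Net-radiation extinction coefficient through the canopy
#'   (Beer-Lambert, > 0).
#' @param k_par PAR extinction coefficient used to invert LAI from canopy
#'   cover (> 0).
#' @param savi_slope,savi_offset Linear NDVI to SAVI proxy
#'   (`SAVI = savi_slope * NDVI + savi_offset`).
#' @param fapar_slope,fapar_offset Linear SAVI to fAPAR mapping, clipped to
#'   `[0, 1]`.
#' @param fipar_slope,fipar_offset Linear NDVI to fIPAR mapping, clipped to
#'   `[0, 1]`.
#' @param topt Temperature optimum of the plant temperature constraint
#'   (degC, > 0). Usually replaced by [estimate_topt()].
#' @param lambda_v Latent heat of vaporization (J/kg); approx. 2260 kJ/kg.
#' @param g_amplitude Amplitude A of the diurnal soil-heat-flux cosine
#'   (fraction of soil net radiation).
#' @param g_period Period B of the soil-heat-flux cosine (seconds).
#'
#' @return An object of class `ptjpl_params` (a validated named list).
#' @seealso [compute_fluxes()], [vegetation_indices()], [soil_heat_flux()]
#' @export
#' @examples
#' p <- ptjpl_params()
#' p$alpha
ptjpl_params <- function(alpha = 1.26,
                         beta = 1.0,
                         gamma = 0.066,
                         k_rn = 0.6,
                         k_par = 0.5,
                         savi_slope = 0.45,
                         savi_offset = 0.132,
                         fapar_slope = 1.3632,
                         fapar_offset = -0.048,
                         fipar_slope = 1.0,
                         fipar_offset = -0.05,
                         topt = 25,
                         lambda_v = 2.26e6,
                         g_amplitude = 0.31,
                         g_period = 74000) {
  p <- list(alpha = alpha, beta = beta, gamma = gamma,
            k_rn = k_rn, k_par = k_par,
            savi_slope = savi_slope, savi_offset = savi_offset,
            fapar_slope = fapar_slope, fapar_offset = fapar_offset,
            fipar_slope = fipar_slope, fipar_offset = fipar_offset,
            topt = topt, lambda_v = lambda_v,
            g_amplitude = g_amplitude, g_period = g_period)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("ptjpl_params: '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (alpha <= 0) stop("ptjpl_params: alpha must be > 0", call. = FALSE)
  if (beta <= 0) stop("ptjpl_params: beta must be > 0", call. = FALSE)
  if (gamma <= 0) stop("ptjpl_params: gamma must be > 0", call. = FALSE)
  if (k_rn <= 0 || k_par <= 0) {
    stop("ptjpl_params: extinction coefficients must be > 0", call. = FALSE)
  }
  if (lambda_v <= 0) stop("ptjpl_params: lambda_v must be > 0", call. = FALSE)
  if (g_period <= 0) stop("ptjpl_params: g_period must be > 0", call. = FALSE)
  structure(p, class = "ptjpl_params")
}

#' @export
print.ptjpl_params <- function(x, ...) {
  cat("PT-JPL parameters\n")
  cat(sprintf("  alpha = %.3f, beta = %.3f kPa, gamma = %.3f kPa/degC\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  k_rn = %.2f, k_par = %.2f, topt = %.1f degC\n",
              x$k_rn, x$k_par, x$topt))
  cat(sprintf("  NDVI->SAVI: %.3f x + %.3f; SAVI->fAPAR: %.4f x + %.3f; NDVI->fIPAR: %.2f x + %.2f\n",
              x$savi_slope, x$savi_offset, x$fapar_slope, x$fapar_offset,
              x$fipar_slope, x$fipar_offset))
  cat(sprintf("  lambda_v = %.3g J/kg; G: A = %.2f, B = %g s\n",
              x$lambda_v, x$g_amplitude, x$g_period))
  invisible(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
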