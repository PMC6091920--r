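# Textbook meteorological helper quantities. All functions are pure,
# vectorized over records, and propagate missing values.

#' Latent heat of vaporization
#'
#' Linear approximation of the latent heat of vaporization of water as a
#' function of air temperature.
#'
#' @param Ta Air temperature (deg C).
#' @return Latent heat of vaporization (J kg-1).
#' @examples
#' latent_heat_vaporization(25)  # 2.44175e6
#' @export
latent_heat_vaporization <- function(Ta) {
  (2.501 - 0.00237 * Ta) * 1e+06
}

#' Saturation vapor pressure and slope of the saturation curve
#'
#' Magnus-type saturation vapor pressure over water and its analytic
#' derivative with respect to temperature.
#'
#' @param Ta Air temperature (deg C).
#' @param formula Coefficient set: `"Sonntag_1990"` (default) or
#'   `"Alduchov_1996"`.
#' @param constants Constants list (unused, kept for interface uniformity).
#' @return A data.frame with columns `esat` (kPa) and `delta` (kPa K-1).
#' @examples
#' esat_slope(20)$esat  # ~2.33 kPa
#' @export
esat_slope <- function(Ta, formula = c("Sonntag_1990", "Alduchov_1996"),
                       constants = flux_constants()) {
  formula <- match.arg(formula)
  if (formula == "Sonntag_1990") {
    a <- 611.2; b <- 17.62; c <- 243.12
  } else {
    a <- 610.94; b <- 17.625; c <- 243.04
  }
  esat <- a * 0.001 * exp(b * Ta / (c + Ta))
  delta <- esat * b * c / (c + Ta)^2
  data.frame(esat = esat, delta = delta)
}

#' Psychrometric constant
#'
#' @param Ta Air temperature (deg C).
#' @param p Atmospheric pressure (kPa).
#' @param constants Constants list, see [flux_constants()].
#' @return Psychrometric constant (kPa K-1), `cp * p / (eps * lambda(Ta))`.
#' @examples
#' psychrometric_constant(25, 101.325)  # ~0.0670
#' @export
psychrometric_constant <- function(Ta, p, constants = flux_constants()) {
  constants$cp * p / (constants$eps * latent_heat_vaporization(Ta))
}

#' Air density
#'
#' Dry-air density from the ideal gas law. The moisture correction (at most
#' a few per mil under eddy covariance conditions) can be applied by passing
#' the virtual temperature instead of `Ta`.
#'
#' @param Ta Air temperature (deg C).
#' @param p Atmospheric pressure (kPa).
#' @param constants Constants list, see [flux_constants()].
#' @return Air density (kg m-3).
#' @examples
#' air_density(25, 101.325)  # ~1.184
#' @export
air_density <- function(Ta, p, constants = flux_constants()) {
  1000 * p / (constants$Rd * (Ta + constants$Kelvin))
}

#' Virtual temperature
#'
#' @param Ta Air temperature (deg C).
#' @param q Specific humidity (kg kg-1).
#' @param method `"approx"` uses `Tv = T * (1 + 0.61 q)`; `"exact"` uses the
#'   full epsilon form `Tv = T / (1 - (1 - eps) * e / p)` and then requires
#'   `p` (kPa).
#' @param p Atmospheric pressure (kPa), exact form only.
#' @param constants Constants list, see [flux_constants()].
#' @return Virtual temperature (K).
#' @export
virtual_temp <- function(Ta, q, method = c("approx", "exact"), p = NULL,
                         constants = flux_constants()) {
  method <- match.arg(method)
  TaK <- Ta + constants$Kelvin
  if (method == "approx") {
    TaK * (1 + 0.61 * q)
  } else {
    if (is.null(p)) stop("exact virtual temperature requires p")
    e <- q_to_e(q, p, constants)
    TaK / (1 - (1 - constants$eps) * e / p)
  }
}

# Bisection for the scalar psychrometric solvers: finds T in [lower, Ta]
# with f(T) = 0, tolerance on |f|.
.bisect_temp <- function(f, Ta, lower = -100, tol = 1e-06, max_iter = 200) {
  lo <- lower
  hi <- Ta
  flo <- f(lo)
  fhi <- f(hi)
  if (is.na(flo) || is.na(fhi)) return(NA_real_)
  if (flo * fhi > 0) stop("temperature solver: no sign change on bracket")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fmid <- f(mid)
    if (abs(fmid) < tol) return(mid)
    if (flo * fmid <= 0) {
      hi <- mid
    } else {
      lo <- mid
      flo <- fmid
    }
  }
  stop("temperature solver did not converge after ", max_iter,
       " iterations (residual ", signif(f((lo + hi) / 2), 3), " kPa)")
}

#' Wet-bulb temperature
#'
#' Solves `esat(Tw) - gamma * (Ta - Tw) = e_a` for `Tw` by bisection on
#' `[-100, Ta]` (tolerance 1e-6 kPa, at most 200 iterations).
#'
#' @param Ta Air temperature (deg C).
#' @param p Atmospheric pressure (kPa).
#' @param Da Vapor pressure deficit (kPa).
#' @param formula Saturation vapor pressure formula, see [esat_slope()].
#' @param constants Constants list, see [flux_constants()].
#' @return Wet-bulb temperature (deg C).
#' @export
wetbulb_temp <- function(Ta, p, Da, formula = c("Sonntag_1990", "Alduchov_1996"),
                         constants = flux_constants()) {
  formula <- match.arg(formula)
  gamma <- psychrometric_constant(Ta, p, constants)
  ea <- VPD_to_e(Da, Ta, formula, constants)
  mapply(function(Ta_i, g_i, e_i) {
    if (anyNA(c(Ta_i, g_i, e_i)) || e_i <= 0) return(NA_real_)
    if (e_i >= esat_slope(Ta_i, formula, constants)$esat) return(Ta_i)
    .bisect_temp(function(Tw) {
      esat_slope(Tw, formula, constants)$esat - g_i * (Ta_i - Tw) - e_i
    }, Ta_i)
  }, Ta, gamma, ea)
}

#' Dew point
#'
#' Solves `esat(Td) = e_a` for `Td` by bisection (tolerance 1e-6 kPa).
#'
#' @inheritParams wetbulb_temp
#' @return Dew point temperature (deg C).
#' @export
dew_point <- function(Ta, Da, formula = c("Sonntag_1990", "Alduchov_1996"),
                      constants = flux_constants()) {
  formula <- match.arg(formula)
  ea <- VPD_to_e(Da, Ta, formula, constants)
  mapply(function(Ta_i, e_i) {
    if (anyNA(c(Ta_i, e_i)) || e_i <= 0) return(NA_real_)
    if (e_i >= esat_slope(Ta_i, formula, constants)$esat) return(Ta_i)
    .bisect_temp(function(Td) {
      esat_slope(Td, formula, constants)$esat - e_i
    }, Ta_i)
  }, Ta, ea)
}

#' Atmospheric pressure from elevation
#'
#' Hypsometric equation with a virtual-temperature correction. The pressure
#' entering the humidity correction is first estimated with the dry form,
#' then refined once.
#'
#' @param elev Site elevation above sea level (m).
#' @param Ta Air temperature (deg C).
#' @param Da Vapor pressure deficit (kPa); 0 assumes saturation.
#' @param formula Saturation vapor pressure formula, see [esat_slope()].
#' @param constants Constants list, see [flux_constants()].
#' @return Atmospheric pressure (kPa); `pressure0` (101.325) at sea level.
#' @examples
#' pressure_from_elevation(1000, Ta = 15, Da = 0)  # ~90.1 kPa
#' @export
pressure_from_elevation <- function(elev, Ta, Da = 0,
                                    formula = c("Sonntag_1990", "Alduchov_1996"),
                                    constants = flux_constants()) {
  formula <- match.arg(formula)
  TaK <- Ta + constants$Kelvin
  p1 <- constants$pressure0 * exp(-constants$g * elev / (constants$Rd * TaK))
  ea <- VPD_to_e(Da, Ta, formula, constants)
  q <- e_to_q(ea, p1, constants)
  Tv <- virtual_temp(Ta, q, constants = constants)
  constants$pressure0 * exp(-constants$g * elev / (constants$Rd * Tv))
}

#' Kinematic viscosity of air
#'
#' @param Ta Air temperature (deg C).
#' @param p Atmospheric pressure (kPa).
#' @param constants Constants list, see [flux_constants()].
#' @return Kinematic viscosity (m2 s-1), scaled from the reference value at
#'   273.15 K and 101.325 kPa with a T^1.81 temperature dependence.
#' @export
kinematic_viscosity <- function(Ta, p, constants = flux_constants()) {
  constants$nu0 * (constants$pressure0 / p) *
    ((Ta + constants$Kelvin) / constants$Tair0)^1.81
}
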