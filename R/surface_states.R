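# Conditions at the notional big-leaf surface: inversion of the bulk
# transfer relations, and the radiometric surface temperature.

#' Meteorological conditions at the big-leaf surface
#'
#' Inverts the bulk transfer relations to estimate temperature, vapor
#' pressure, vapor pressure deficit, specific and relative humidity, and
#' CO2 concentration at the notional canopy surface:
#' \deqn{T_s = T_a + H / (rho G_{ah} c_p)}
#' \deqn{e_s = e_a + LE \gamma / (rho G_{ah} c_p)}
#' \deqn{D_s = e_{sat}(T_s) - e_s}
#' \deqn{C_s = C_a + NEE / G_{ac}}
#' With the sign convention used here (fluxes away from the surface
#' positive), daytime CO2 uptake (negative NEE) gives `Cs < Ca`. Passing
#' momentum-only conductances (`Gam` in place of `Gah`/`Gac`) targets the
#' intercanopy airspace instead of the canopy surface.
#'
#' @param Ta Air temperature (deg C).
#' @param p Atmospheric pressure (kPa).
#' @param H Sensible heat flux (W m-2).
#' @param LE Latent heat flux (W m-2); omit (NULL) to skip humidity outputs.
#' @param Gah Aerodynamic conductance to heat (m s-1); non-positive values
#'   propagate as missing.
#' @param Da Air vapor pressure deficit (kPa), used to derive `e_a`;
#'   alternatively give `e_a` directly.
#' @param e_a Air vapor pressure (kPa).
#' @param Ca Air CO2 concentration (umol mol-1), optional.
#' @param NEE Net ecosystem exchange (umol m-2 s-1), optional.
#' @param Gac_mol Aerodynamic conductance to CO2 in molar units
#'   (mol m-2 s-1), required for `Cs`.
#' @param rho Air density (kg m-3); computed from `Ta`, `p` when NULL.
#' @param gamma Psychrometric constant (kPa K-1); computed when NULL.
#' @param formula Saturation vapor pressure formula, see [esat_slope()].
#' @param constants Constants list, see [flux_constants()].
#'
#' @return A data.frame with columns `Ts` (deg C), `esat_Ts`, `es`, `Ds`
#'   (kPa), `qs` (kg kg-1), `rHs` (0..1; values above 1 are kept and
#'   signalled by the logical column `supersaturated`), and `Cs`
#'   (umol mol-1).
#' @examples
#' surface_conditions(Ta = 25, p = 101.325, H = 200, LE = 150, Gah = 0.1,
#'                    Da = 1.5)
#' @export
surface_conditions <- function(Ta, p, H, LE = NULL, Gah, Da = NULL,
                               e_a = NULL, Ca = NULL, NEE = NULL,
                               Gac_mol = NULL, rho = NULL, gamma = NULL,
                               formula = c("Sonntag_1990", "Alduchov_1996"),
                               constants = flux_constants()) {
  formula <- match.arg(formula)
  Gah <- ifelse(Gah <= 0, NA_real_, Gah)
  if (is.null(rho)) rho <- air_density(Ta, p, constants)
  if (is.null(gamma)) gamma <- psychrometric_constant(Ta, p, constants)

  Ts <- Ta + H / (rho * Gah * constants$cp)
  esat_Ts <- esat_slope(Ts, formula, constants)$esat
  out <- data.frame(Ts = Ts, esat_Ts = esat_Ts)

  if (!is.null(LE)) {
    if (is.null(e_a)) {
      if (is.null(Da)) stop("humidity inversion requires Da or e_a")
      e_a <- VPD_to_e(Da, Ta, formula, constants)
    }
    es <- e_a + LE * gamma / (rho * Gah * constants$cp)
    out$es <- es
    out$Ds <- esat_Ts - es
    out$qs <- e_to_q(es, p, constants)
    out$rHs <- es / esat_Ts
    out$supersaturated <- !is.na(out$rHs) & out$rHs > 1
  }
  if (!is.null(Ca) && !is.null(NEE)) {
    if (is.null(Gac_mol))
      stop("surface CO2 requires Gac_mol (mol m-2 s-1)")
    Gac_mol <- ifelse(Gac_mol <= 0, NA_real_, Gac_mol)
    out$Cs <- Ca + NEE / Gac_mol
  }
  out
}

#' Radiometric surface temperature
#'
#' Inverts the Stefan-Boltzmann relation for the surface temperature seen
#' by the longwave radiometers:
#' `Tr = [(LW_up - (1 - emissivity) * LW_down) / (sigma * emissivity)]^0.25`.
#'
#' @param LW_up Longwave upward radiation (W m-2).
#' @param LW_down Longwave downward radiation (W m-2).
#' @param emissivity Surface longwave emissivity (0..1), default 0.98.
#' @param constants Constants list, see [flux_constants()].
#' @return Radiometric surface temperature (K); a non-positive radicand
#'   propagates as missing.
#' @export
radiometric_surface_temp <- function(LW_up, LW_down, emissivity = 0.98,
                                     constants = flux_constants()) {
  if (any(emissivity <= 0 | emissivity > 1, na.rm = TRUE))
    stop("emissivity must be in (0, 1]")
  radicand <- (LW_up - (1 - emissivity) * LW_down) /
    (constants$sigma * emissivity)
  ifelse(radicand <= 0, NA_real_, radicand^0.25)
}
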