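# Unit interconversions. All functions are vectorized, propagate NA, and are
# exact inverses of their counterparts on the valid domain.
#
# Sign convention throughout the package: fluxes directed away from the
# surface are positive (negative NEE = net CO2 uptake by the ecosystem).

#' Conductance conversion between mass and molar units
#'
#' Converts conductances between m s-1 and mol m-2 s-1 using the molar
#' density of air from the ideal gas law.
#'
#' @param G Conductance (m s-1 for `ms_to_mol`, mol m-2 s-1 for `mol_to_ms`).
#' @param Ta Air temperature (deg C).
#' @param p Atmospheric pressure (kPa).
#' @param constants Constants list, see [flux_constants()].
#'
#' @details `G_mol = G_ms * 1000 * p / (Rgas * (Ta + 273.15))`. The inverse
#' direction divides by the same molar density, so round trips are exact.
#'
#' @return Conductance in the target unit.
#' @examples
#' ms_to_mol(0.01, Ta = 25, p = 101.325)  # ~0.4087 mol m-2 s-1
#' @export
ms_to_mol <- function(G, Ta, p, constants = flux_constants()) {
  G * 1000 * p / (constants$Rgas * (Ta + constants$Kelvin))
}

#' @rdname ms_to_mol
#' @export
mol_to_ms <- function(G, Ta, p, constants = flux_constants()) {
  G * constants$Rgas * (Ta + constants$Kelvin) / (1000 * p)
}

#' Water flux conversion between energy and mass units
#'
#' @param LE Latent heat flux (W m-2).
#' @param ET Evapotranspiration (kg m-2 s-1).
#' @param Ta Air temperature (deg C), used for the latent heat of
#'   vaporization.
#' @return `LE_to_ET`: ET (kg m-2 s-1); `ET_to_LE`: LE (W m-2).
#' @examples
#' LE_to_ET(244.175, Ta = 25)  # 1e-4 kg m-2 s-1
#' @export
LE_to_ET <- function(LE, Ta) {
  LE / latent_heat_vaporization(Ta)
}

#' @rdname LE_to_ET
#' @export
ET_to_LE <- function(ET, Ta) {
  ET * latent_heat_vaporization(Ta)
}

#' Carbon flux conversion between molar and mass units
#'
#' Converts CO2 fluxes between umol CO2 m-2 s-1 and g C m-2 d-1. Linear and
#' sign-preserving.
#'
#' @param x Flux to convert.
#' @param constants Constants list, see [flux_constants()].
#' @return Converted flux.
#' @examples
#' umolCO2_to_gC(1)  # ~1.0378 g C m-2 d-1
#' @export
umolCO2_to_gC <- function(x, constants = flux_constants()) {
  x * 1e-06 * constants$Mc * 86400
}

#' @rdname umolCO2_to_gC
#' @export
gC_to_umolCO2 <- function(x, constants = flux_constants()) {
  x / (1e-06 * constants$Mc * 86400)
}

#' Radiation conversion between energy and molar units
#'
#' Converts global (shortwave) radiation to photosynthetic photon flux
#' density and back, assuming a fixed PAR fraction and quanta-per-joule
#' coefficient.
#'
#' @param Rg Global radiation (W m-2).
#' @param PPFD Photosynthetic photon flux density (umol m-2 s-1).
#' @param constants Constants list (`frac_PAR`, `J_to_mol`).
#' @return Converted radiation flux.
#' @examples
#' Rg_to_PPFD(500)  # 1150 umol m-2 s-1
#' @export
Rg_to_PPFD <- function(Rg, constants = flux_constants()) {
  Rg * constants$frac_PAR * constants$J_to_mol
}

#' @rdname Rg_to_PPFD
#' @export
PPFD_to_Rg <- function(PPFD, constants = flux_constants()) {
  PPFD / (constants$frac_PAR * constants$J_to_mol)
}

#' Atmospheric humidity conversions
#'
#' Conversions between vapor pressure deficit (kPa), vapor pressure (kPa),
#' specific humidity (kg kg-1), and relative humidity (0..1), all via the
#' saturation vapor pressure at air temperature.
#'
#' @param rH Relative humidity (0..1).
#' @param VPD Vapor pressure deficit (kPa).
#' @param e Vapor pressure (kPa).
#' @param q Specific humidity (kg kg-1).
#' @param Ta Air temperature (deg C).
#' @param p Atmospheric pressure (kPa).
#' @param formula Saturation vapor pressure formula, see [esat_slope()].
#' @param constants Constants list, see [flux_constants()].
#'
#' @details Specific humidity follows `q = eps * e / (p - (1 - eps) * e)`.
#' Relative humidity outside `[0, 1]` is an error; vapor pressures above
#' saturation (supersaturation, usually an inversion artifact) are kept but
#' flagged with a warning.
#'
#' @return The converted humidity measure.
#' @examples
#' rH_to_VPD(0.5, Ta = 20)
#' VPD_to_q(1.5, Ta = 25, p = 101.325)
#' @name humidity_conversions
NULL

#' @rdname humidity_conversions
#' @export
rH_to_VPD <- function(rH, Ta, formula = c("Sonntag_1990", "Alduchov_1996"),
                      constants = flux_constants()) {
  if (any(rH < 0 | rH > 1, na.rm = TRUE))
    stop("relative humidity must be within [0, 1]")
  (1 - rH) * esat_slope(Ta, formula, constants)$esat
}

#' @rdname humidity_conversions
#' @export
VPD_to_rH <- function(VPD, Ta, formula = c("Sonntag_1990", "Alduchov_1996"),
                      constants = flux_constants()) {
  1 - VPD / esat_slope(Ta, formula, constants)$esat
}

#' @rdname humidity_conversions
#' @export
e_to_VPD <- function(e, Ta, formula = c("Sonntag_1990", "Alduchov_1996"),
                     constants = flux_constants()) {
  esat <- esat_slope(Ta, formula, constants)$esat
  if (any(e > esat, na.rm = TRUE))
    warning("vapor pressure above saturation; negative VPD returned")
  esat - e
}

#' @rdname humidity_conversions
#' @export
VPD_to_e <- function(VPD, Ta, formula = c("Sonntag_1990", "Alduchov_1996"),
                     constants = flux_constants()) {
  esat_slope(Ta, formula, constants)$esat - VPD
}

#' @rdname humidity_conversions
#' @export
e_to_q <- function(e, p, constants = flux_constants()) {
  constants$eps * e / (p - (1 - constants$eps) * e)
}

#' @rdname humidity_conversions
#' @export
q_to_e <- function(q, p, constants = flux_constants()) {
  q * p / (constants$eps + (1 - constants$eps) * q)
}

#' @rdname humidity_conversions
#' @export
VPD_to_q <- function(VPD, Ta, p, formula = c("Sonntag_1990", "Alduchov_1996"),
                     constants = flux_constants()) {
  e_to_q(VPD_to_e(VPD, Ta, formula, constants), p, constants)
}

#' @rdname humidity_conversions
#' @export
q_to_VPD <- function(q, Ta, p, formula = c("Sonntag_1990", "Alduchov_1996"),
                     constants = flux_constants()) {
  e_to_VPD(q_to_e(q, p, constants), Ta, formula, constants)
}
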