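#' Physical constants and conversion coefficients
#'
#' Single registry of the physical constants used throughout the package.
#' Every function that needs a constant takes a `constants` argument
#' defaulting to `flux_constants()`, so individual values can be overridden
#' per call without touching the defaults.
#'
#' @param ... Named overrides for individual constants. Names not present in
#'   the registry raise an error.
#'
#' @return A named list with elements:
#' \describe{
#'   \item{k}{von Karman constant (-)}
#'   \item{Cd}{foliage drag coefficient (-)}
#'   \item{Pr}{Prandtl number (-)}
#'   \item{Sc_CO2}{Schmidt number for CO2 (-)}
#'   \item{g}{gravitational acceleration (m s-2)}
#'   \item{sigma}{Stefan-Boltzmann constant (W m-2 K-4)}
#'   \item{cp}{specific heat of dry air at constant pressure (J K-1 kg-1)}
#'   \item{eps}{ratio of molecular weights of water vapor and dry air (-)}
#'   \item{Rgas}{universal gas constant (J mol-1 K-1)}
#'   \item{Rd}{specific gas constant of dry air (J kg-1 K-1)}
#'   \item{Kelvin}{conversion degree Celsius to Kelvin}
#'   \item{DwDc}{ratio of diffusivities of water vapor and CO2 (-)}
#'   \item{Mw}{molar mass of water vapor (kg mol-1)}
#'   \item{Mc}{molar mass of carbon (g mol-1)}
#'   \item{frac_PAR}{PAR fraction of incoming shortwave radiation (-)}
#'   \item{J_to_mol}{quanta per unit energy of PAR (umol J-1)}
#'   \item{alpha_bioenergy}{energy fixed per unit CO2 flux (J umol-1)}
#'   \item{alpha_PT}{Priestley-Taylor coefficient (-)}
#'   \item{pressure0}{reference (sea-level) pressure (kPa)}
#'   \item{Tair0}{reference air temperature (K)}
#'   \item{nu0}{kinematic viscosity of air at reference conditions (m2 s-1)}
#' }
#'
#' @examples
#' flux_constants()$k
#' flux_constants(Sc_CO2 = 1.05)$Sc_CO2
#'
#' @export
flux_constants <- function(...) {
  cst <- list(
    k        = 0.41,
    Cd       = 0.2,
    Pr       = 0.71,
    Sc_CO2   = 1.07,
    g        = 9.81,
    sigma    = 5.670367e-08,
    cp       = 1004.834,
    eps      = 0.622,
    Rgas     = 8.31451,
    Rd       = 287.0586,
    Kelvin   = 273.15,
    DwDc     = 1.6,
    Mw       = 0.0180153,
    Mc       = 12.011,
    frac_PAR = 0.5,
    J_to_mol = 4.6,
    alpha_bioenergy = 0.422,
    alpha_PT = 1.26,
    pressure0 = 101.325,
    Tair0    = 273.15,
    nu0      = 1.327e-05
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cst))
    if (length(bad) || is.null(names(over)) || any(names(over) == ""))
      stop("unknown constant(s): ", paste(bad, collapse = ", "))
    if (any(vapply(over, function(x) !is.numeric(x) || any(x <= 0), TRUE)))
      stop("constants must be strictly positive numbers")
    cst[names(over)] <- over
  }
  cst
}
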