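# Surface conductance by Penman-Monteith inversion, decoupling, ET
# decomposition, potential ET, and energy-balance diagnostics.

#' Forward big-leaf Penman-Monteith equation
#'
#' Latent heat flux from available energy, vapor pressure deficit, and the
#' two bulk conductances:
#' `LE = (s * A + rho * cp * Gah * Da) / (s + gamma * (1 + Gah / Gsw))`
#' with `A = Rn - G - S`. Exact algebraic inverse of
#' [surface_conductance()] with `method = "PM"`.
#'
#' @param Rn Net radiation (W m-2).
#' @param G Ground heat flux (W m-2), 0 when NULL.
#' @param S Storage heat flux (W m-2), 0 when NULL.
#' @param Ta Air temperature (deg C).
#' @param p Atmospheric pressure (kPa).
#' @param Da Vapor pressure deficit (kPa).
#' @param Gah Aerodynamic conductance to heat (m s-1).
#' @param Gsw Surface conductance to water vapor (m s-1).
#' @param formula Saturation vapor pressure formula, see [esat_slope()].
#' @param constants Constants list, see [flux_constants()].
#' @return Latent heat flux (W m-2).
#' @export
penman_monteith <- function(Rn, G = NULL, S = NULL, Ta, p, Da, Gah, Gsw,
                            formula = c("Sonntag_1990", "Alduchov_1996"),
                            constants = flux_constants()) {
  formula <- match.arg(formula)
  A <- Rn - .zero_if_null(G) - .zero_if_null(S)
  s <- esat_slope(Ta, formula, constants)$delta
  gamma <- psychrometric_constant(Ta, p, constants)
  rho <- air_density(Ta, p, constants)
  (s * A + rho * constants$cp * Gah * Da) /
    (s + gamma * (1 + Gah / Gsw))
}

.zero_if_null <- function(x) if (is.null(x)) 0 else ifelse(is.na(x), 0, x)

#' Surface conductance to water vapor
#'
#' Inverts the Penman-Monteith equation for the bulk surface conductance
#' (`method = "PM"`):
#' `Gsw = LE * Gah * gamma / (s * (Rn - G - S) + rho * cp * Gah * Da
#'  - LE * (s + gamma))`,
#' or uses a simple flux-gradient form assuming infinite aerodynamic
#' conductance (`method = "flux_gradient"`): `Gsw = (LE / lambda) / (Mw *
#' Da / p)` in mol m-2 s-1.
#'
#' Missing `G`/`S` columns are treated as zero. Negative derived values
#' (possible under weak gradients or energy-balance problems) are returned
#' as-is and marked in the `flag` column: filtering is an explicit separate
#' stage, see [filter_data()].
#'
#' @param Rn Net radiation (W m-2).
#' @param G Ground heat flux (W m-2), optional.
#' @param S Storage heat flux (W m-2), optional.
#' @param LE Latent heat flux (W m-2).
#' @param Da Vapor pressure deficit (kPa).
#' @param Ta Air temperature (deg C).
#' @param p Atmospheric pressure (kPa).
#' @param Gah Aerodynamic conductance to heat (m s-1), PM method.
#' @param method `"PM"` (default) or `"flux_gradient"`.
#' @param formula Saturation vapor pressure formula, see [esat_slope()].
#' @param constants Constants list, see [flux_constants()].
#'
#' @return A data.frame with `Gsw_ms` (m s-1), `Gsw_mol` (mol m-2 s-1), and
#'   a character `flag` column (`"ok"`, `"negative"`, `"zero_denominator"`).
#' @examples
#' surface_conductance(Rn = 400, LE = 200, Da = 1.5, Ta = 25, p = 101.325,
#'                     Gah = 0.1)
#' @export
surface_conductance <- function(Rn = NULL, G = NULL, S = NULL, LE, Da, Ta, p,
                                Gah = NULL,
                                method = c("PM", "flux_gradient"),
                                formula = c("Sonntag_1990", "Alduchov_1996"),
                                constants = flux_constants()) {
  method <- match.arg(method)
  formula <- match.arg(formula)
  if (method == "PM") {
    if (is.null(Rn)) stop("PM inversion requires Rn")
    if (is.null(Gah)) stop("PM inversion requires Gah")
    A <- Rn - .zero_if_null(G) - .zero_if_null(S)
    s <- esat_slope(Ta, formula, constants)$delta
    gamma <- psychrometric_constant(Ta, p, constants)
    rho <- air_density(Ta, p, constants)
    denom <- s * A + rho * constants$cp * Gah * Da - LE * (s + gamma)
    zero_den <- !is.na(denom) & denom == 0
    Gsw_ms <- ifelse(zero_den, NA_real_, LE * Gah * gamma / denom)
    Gsw_mol <- ms_to_mol(Gsw_ms, Ta, p, constants)
  } else {
    lambda <- latent_heat_vaporization(Ta)
    Gsw_mol <- (LE / lambda) / (constants$Mw * Da / p)
    Gsw_ms <- mol_to_ms(Gsw_mol, Ta, p, constants)
    zero_den <- rep(FALSE, length(Gsw_mol))
  }
  flag <- rep("ok", length(Gsw_ms))
  flag[!is.na(Gsw_ms) & Gsw_ms < 0] <- "negative"
  flag[zero_den] <- "zero_denominator"
  data.frame(Gsw_ms = Gsw_ms, Gsw_mol = Gsw_mol, flag = flag)
}

#' Longwave radiative transfer conductance of the canopy
#'
#' `Gr = 4 * sigma * (Ta + 273.15)^3 * LAI / cp`, as conventionally printed.
#' Note the printed form carries units of kg m-2 s-1; dividing by air
#' density (`normalize_rho = TRUE`) gives strict m s-1. The default keeps
#' the printed form.
#'
#' @param Ta Air temperature (deg C).
#' @param LAI Leaf area index (-).
#' @param normalize_rho Divide by air density?
#' @param p Atmospheric pressure (kPa), only with `normalize_rho`.
#' @param constants Constants list, see [flux_constants()].
#' @return Radiative transfer conductance.
#' @export
longwave_conductance <- function(Ta, LAI, normalize_rho = FALSE, p = NULL,
                                 constants = flux_constants()) {
  Gr <- 4 * constants$sigma * (Ta + constants$Kelvin)^3 * LAI / constants$cp
  if (normalize_rho) {
    if (is.null(p)) stop("normalize_rho requires p")
    Gr <- Gr / air_density(Ta, p, constants)
  }
  Gr
}

#' Vegetation-atmosphere decoupling coefficient
#'
#' Degree of aerodynamic decoupling between the canopy and the atmosphere
#' (0 = fully coupled, ET controlled by surface conductance and VPD; 1 =
#' fully decoupled, ET controlled by available energy):
#' \deqn{\Omega_{Jarvis} = (s/\gamma + 1) /
#'   (s/\gamma + 1 + G_{ah}/G_{sw})}
#' The Martin formulation adds the radiative coupling terms via the
#' longwave transfer conductance `Gr` and reduces exactly to the Jarvis
#' form at `Gr = 0`.
#'
#' @param Gsw Surface conductance to water vapor (m s-1).
#' @param Gah Aerodynamic conductance to heat (m s-1).
#' @param Ta Air temperature (deg C).
#' @param p Atmospheric pressure (kPa).
#' @param formulation `"Jarvis_McNaughton"` (default) or `"Martin"`.
#' @param Gr Longwave radiative transfer conductance (m s-1), Martin
#'   formulation, see [longwave_conductance()].
#' @param formula Saturation vapor pressure formula, see [esat_slope()].
#' @param constants Constants list, see [flux_constants()].
#' @return Decoupling coefficient (0..1); non-positive conductances
#'   propagate as missing.
#' @export
decoupling <- function(Gsw, Gah, Ta, p,
                       formulation = c("Jarvis_McNaughton", "Martin"),
                       Gr = NULL,
                       formula = c("Sonntag_1990", "Alduchov_1996"),
                       constants = flux_constants()) {
  formulation <- match.arg(formulation)
  formula <- match.arg(formula)
  Gsw <- ifelse(Gsw <= 0, NA_real_, Gsw)
  Gah <- ifelse(Gah <= 0, NA_real_, Gah)
  sg <- esat_slope(Ta, formula, constants)$delta /
    psychrometric_constant(Ta, p, constants)
  if (formulation == "Jarvis_McNaughton") {
    (sg + 1) / (sg + 1 + Gah / Gsw)
  } else {
    if (is.null(Gr)) stop("Martin formulation requires Gr")
    (sg + 1 + Gr / Gah) /
      (sg + 1 + Gah / Gsw + Gr / Gsw + Gr / Gah)
  }
}

#' Equilibrium and imposed evapotranspiration
#'
#' The two Penman-Monteith limits: `LE_eq = s * (Rn - G - S) / (s + gamma)`
#' (aerodynamic conductance approaching zero, radiation-controlled) and
#' `LE_imp = rho * cp * Gsw * Da / gamma` (aerodynamic conductance
#' approaching infinity, VPD/stomata-controlled). The omega-weighted sum
#' `Omega * LE_eq + (1 - Omega) * LE_imp` recovers the forward
#' Penman-Monteith flux exactly.
#'
#' @inheritParams penman_monteith
#' @return A data.frame with columns `LE_eq` and `LE_imp` (W m-2).
#' @export
equilibrium_imposed_ET <- function(Rn, G = NULL, S = NULL, Ta, p, Da, Gsw,
                                   formula = c("Sonntag_1990",
                                               "Alduchov_1996"),
                                   constants = flux_constants()) {
  formula <- match.arg(formula)
  A <- Rn - .zero_if_null(G) - .zero_if_null(S)
  s <- esat_slope(Ta, formula, constants)$delta
  gamma <- psychrometric_constant(Ta, p, constants)
  rho <- air_density(Ta, p, constants)
  data.frame(LE_eq = s * A / (s + gamma),
             LE_imp = rho * constants$cp * Gsw * Da / gamma)
}

#' Potential evapotranspiration
#'
#' Priestley-Taylor form `LE_pot = alpha_PT * s * (Rn - G - S) / (s +
#' gamma)` (default `alpha_PT = 1.26`), or the Penman-Monteith equation
#' with a prescribed reference surface conductance (a typical maximum, e.g.
#' the 95 percent quantile of the derived `Gsw`).
#'
#' @inheritParams penman_monteith
#' @param method `"PriestleyTaylor"` (default) or `"PenmanMonteith"`.
#' @param alpha_PT Priestley-Taylor coefficient (-).
#' @param Gsw_ref Reference surface conductance (m s-1), PM method.
#' @return Potential latent heat flux (W m-2).
#' @export
potential_ET <- function(method = c("PriestleyTaylor", "PenmanMonteith"),
                         Rn, G = NULL, S = NULL, Ta, p, Da = NULL,
                         Gah = NULL, alpha_PT = NULL, Gsw_ref = NULL,
                         formula = c("Sonntag_1990", "Alduchov_1996"),
                         constants = flux_constants()) {
  method <- match.arg(method)
  formula <- match.arg(formula)
  if (method == "PriestleyTaylor") {
    if (is.null(alpha_PT)) alpha_PT <- constants$alpha_PT
    A <- Rn - .zero_if_null(G) - .zero_if_null(S)
    s <- esat_slope(Ta, formula, constants)$delta
    gamma <- psychrometric_constant(Ta, p, constants)
    alpha_PT * s * A / (s + gamma)
  } else {
    if (is.null(Gah) || is.null(Gsw_ref) || is.null(Da))
      stop("PenmanMonteith potential ET requires Da, Gah and Gsw_ref")
    penman_monteith(Rn, G, S, Ta, p, Da, Gah, Gsw_ref, formula, constants)
  }
}

#' Energy balance closure diagnostics
#'
#' Quantifies closure of the surface energy balance
#' `Rn - G - S = LE + H` with both the ordinary-least-squares slope method
#' (regressing `LE + H` on `Rn - G - S`) and the energy balance ratio
#' `EBR = sum(LE + H) / sum(Rn - G - S)`, over the records where all terms
#' are present.
#'
#' @param data Data frame with columns `Rn`, `LE`, `H`, and optionally `G`,
#'   `S` (treated as zero when absent).
#' @return A list with `slope`, `intercept` (W m-2), `r_squared`, `EBR`,
#'   and `n` (records used).
#' @export
energy_closure <- function(data) {
  .check_columns(data, c("Rn", "LE", "H"))
  G <- if ("G" %in% names(data)) data$G else 0
  S <- if ("S" %in% names(data)) data$S else 0
  A <- data$Rn - ifelse(is.na(G), 0, G) - ifelse(is.na(S), 0, S)
  turb <- data$LE + data$H
  ok <- !is.na(A) & !is.na(turb)
  if (sum(ok) < 2) stop("energy_closure requires at least 2 complete records")
  fit <- stats::lm(turb[ok] ~ A[ok])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit))$r.squared,
       EBR = sum(turb[ok]) / sum(A[ok]),
       n = sum(ok))
}

#' Biochemical energy flux and energy use efficiency
#'
#' `biochemical_energy` estimates the (small, often neglected) energy
#' balance component fixed or released by net CO2 exchange,
#' `Sp = alpha_bioenergy * NEE` (W m-2 with NEE in umol m-2 s-1, keeping
#' the package sign convention, so net uptake gives negative `Sp`).
#' `energy_use_efficiency` reports `EUE = -Sp / Rn`, signed so that net
#' carbon uptake yields a positive efficiency.
#'
#' @param NEE Net ecosystem exchange (umol CO2 m-2 s-1).
#' @param Rn Net radiation (W m-2); zero propagates as missing.
#' @param constants Constants list, see [flux_constants()].
#' @return `biochemical_energy`: Sp (W m-2);
#'   `energy_use_efficiency`: EUE (-).
#' @export
biochemical_energy <- function(NEE, constants = flux_constants()) {
  constants$alpha_bioenergy * NEE
}

#' @rdname biochemical_energy
#' @export
energy_use_efficiency <- function(NEE, Rn, constants = flux_constants()) {
  Sp <- biochemical_energy(NEE, constants)
  ifelse(Rn == 0, NA_real_, -Sp / Rn)
}
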