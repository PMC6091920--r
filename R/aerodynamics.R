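# Aerodynamic conductance: roughness parameters, Monin-Obukhov stability,
# wind profile, and the canopy boundary layer conductance models.

#' Monin-Obukhov stability parameter
#'
#' Computes the Monin-Obukhov length `L` and the dimensionless stability
#' parameter `zeta = (zr - d) / L` from friction velocity, sensible heat
#' flux, and the state of the air.
#'
#' @param zr Reference (measurement) height (m).
#' @param d Zero-plane displacement height (m).
#' @param ustar Friction velocity (m s-1).
#' @param H Sensible heat flux (W m-2).
#' @param Ta Air temperature (deg C).
#' @param q Specific humidity (kg kg-1), for the virtual temperature.
#' @param p Atmospheric pressure (kPa).
#' @param constants Constants list, see [flux_constants()].
#'
#' @details `L = -(ustar^3 * rho * cp * Tv) / (k * g * H)`. A zero heat flux
#' gives the neutral limit `zeta = 0` (`L` infinite); non-positive `ustar`
#' propagates as missing.
#'
#' @return A data.frame with columns `zeta` (-) and `L` (m).
#' @export
stability_parameter <- function(zr, d, ustar, H, Ta, q = 0, p,
                                constants = flux_constants()) {
  ustar <- ifelse(ustar <= 0, NA_real_, ustar)
  rho <- air_density(Ta, p, constants)
  Tv <- virtual_temp(Ta, q, constants = constants)
  L <- ifelse(H == 0, Inf,
              -(ustar^3 * rho * constants$cp * Tv) /
                (constants$k * constants$g * H))
  data.frame(zeta = (zr - d) / L, L = L)
}

#' Integrated stability correction functions
#'
#' Integrated forms of the Monin-Obukhov similarity corrections for heat and
#' water vapor (`psi_h`) and momentum (`psi_m`).
#'
#' @param zeta Stability parameter (-); negative = unstable.
#' @param formulation `"Dyer_1970"` (default) or `"Businger_1971"`.
#'
#' @details For the Dyer formulation, unstable conditions use
#' `x = (1 - 16 zeta)^0.25` with
#' `psi_h = 2 ln[(1 + x^2)/2]` and
#' `psi_m = 2 ln[(1 + x)/2] + ln[(1 + x^2)/2] - 2 atan(x) + pi/2`;
#' stable conditions use `psi_h = psi_m = -5 zeta`. The Businger formulation
#' applies its published coefficients analogously. `zeta = 0` belongs to the
#' neutral branch (`psi = 0`), keeping both branches continuous.
#'
#' @return A data.frame with columns `psi_h` and `psi_m` (-).
#' @examples
#' stability_correction(-0.1)   # psi_h ~ 0.534
#' stability_correction(0.1)    # psi_h = -0.5
#' @export
stability_correction <- function(zeta,
                                 formulation = c("Dyer_1970", "Businger_1971")) {
  formulation <- match.arg(formulation)
  psi_h <- psi_m <- rep(NA_real_, length(zeta))
  unstable <- !is.na(zeta) & zeta < 0
  stable <- !is.na(zeta) & zeta >= 0
  if (formulation == "Dyer_1970") {
    x <- (1 - 16 * zeta[unstable])^0.25
    psi_h[unstable] <- 2 * log((1 + x^2) / 2)
    psi_m[unstable] <- 2 * log((1 + x) / 2) + log((1 + x^2) / 2) -
      2 * atan(x) + pi / 2
    psi_h[stable] <- -5 * zeta[stable]
    psi_m[stable] <- -5 * zeta[stable]
  } else {
    x_h <- 0.95 * (1 - 11.6 * zeta[unstable])^0.5
    x_m <- (1 - 19.3 * zeta[unstable])^0.25
    psi_h[unstable] <- 2 * log((1 + x_h) / 2)
    psi_m[unstable] <- 2 * log((1 + x_m) / 2) + log((1 + x_m^2) / 2) -
      2 * atan(x_m) + pi / 2
    psi_h[stable] <- -7.8 * zeta[stable]
    psi_m[stable] <- -6 * zeta[stable]
  }
  data.frame(psi_h = psi_h, psi_m = psi_m)
}

#' Roughness parameters of the vegetated surface
#'
#' Estimates the zero-plane displacement height `d` and the roughness length
#' for momentum `z0m` with one of three approaches.
#'
#' @param method One of:
#'   \describe{
#'     \item{`"canopy_height"`}{empirical constant fractions of canopy
#'       height: `d = frac_d * zh`, `z0m = frac_z0m * zh`.}
#'     \item{`"canopy_height_LAI"`}{semi-empirical form using canopy height
#'       and leaf area index, with `X = Cd * LAI`:
#'       `d = 1.1 * zh * ln(1 + X^0.25)`;
#'       `z0m = z0m_ground + 0.3 * zh * X^0.5` for `0 < X <= 0.2`, otherwise
#'       `z0m = 0.3 * zh * (1 - d/zh)`.}
#'     \item{`"wind_profile"`}{inverts the logarithmic wind profile per
#'       record for `z0m` with a prescribed `d` and takes the median.}
#'   }
#' @param zh Canopy height (m).
#' @param zr Reference height (m), wind-profile method.
#' @param LAI Leaf area index (-), `canopy_height_LAI` method.
#' @param frac_d,frac_z0m Fractions of canopy height for the empirical
#'   method (defaults 0.7 and 0.1).
#' @param z0m_ground Ground-surface roughness length (m) entering the
#'   low-density branch of the LAI method.
#' @param data Data frame with columns `u`, `ustar` (and `Ta`, `p`, `H` when
#'   `stab_correction = TRUE`), wind-profile method.
#' @param d_prescribed Prescribed displacement height (m), wind-profile
#'   method; defaults to `frac_d * zh`.
#' @param stab_correction Apply the stability correction per record when
#'   inverting the wind profile?
#' @param stability_formulation See [stability_correction()].
#' @param ustar_min Records with `ustar` below this threshold (m s-1) are
#'   discarded before taking the median (wind-profile method).
#' @param constants Constants list, see [flux_constants()].
#'
#' @return A list with elements `d` (m), `z0m` (m), and `method`.
#' @examples
#' roughness_parameters("canopy_height", zh = 26.5)  # d = 18.55, z0m = 2.65
#' @export
roughness_parameters <- function(method = c("canopy_height",
                                            "canopy_height_LAI",
                                            "wind_profile"),
                                 zh, zr = NULL, LAI = NULL,
                                 frac_d = 0.7, frac_z0m = 0.1,
                                 z0m_ground = 0.01,
                                 data = NULL, d_prescribed = NULL,
                                 stab_correction = TRUE,
                                 stability_formulation = "Dyer_1970",
                                 ustar_min = 0.2,
                                 constants = flux_constants()) {
  method <- match.arg(method)
  if (any(zh <= 0)) stop("zh must be positive")
  if (method == "canopy_height") {
    d <- frac_d * zh
    z0m <- frac_z0m * zh
  } else if (method == "canopy_height_LAI") {
    if (is.null(LAI)) stop("canopy_height_LAI method requires LAI")
    X <- constants$Cd * LAI
    d <- 1.1 * zh * log(1 + X^0.25)
    z0m <- ifelse(X > 0 & X <= 0.2,
                  z0m_ground + 0.3 * zh * X^0.5,
                  0.3 * zh * (1 - d / zh))
  } else {
    if (is.null(data)) stop("wind_profile method requires data")
    if (is.null(zr)) stop("wind_profile method requires zr")
    .check_columns(data, c("u", "ustar"))
    d <- if (is.null(d_prescribed)) frac_d * zh else d_prescribed
    if (stab_correction) {
      .check_columns(data, c("Ta", "p", "H"))
      q <- if ("q" %in% names(data)) data$q else 0
      zeta <- stability_parameter(zr, d, data$ustar, data$H, data$Ta, q,
                                  data$p, constants)$zeta
      psi_m <- stability_correction(pmin(pmax(zeta, -15), 15),
                                    stability_formulation)$psi_m
    } else {
      psi_m <- 0
    }
    z0m_i <- (zr - d) * exp(-constants$k * data$u / data$ustar - psi_m)
    z0m_i[data$ustar < ustar_min] <- NA_real_
    z0m <- stats::median(z0m_i, na.rm = TRUE)
  }
  list(d = d, z0m = z0m, method = method)
}

#' Wind speed at a given height from the logarithmic wind profile
#'
#' @param z Height for which wind speed is sought (m); must exceed
#'   `d + z0m`, lower heights are reported missing with a warning.
#' @param ustar Friction velocity (m s-1).
#' @param d Zero-plane displacement height (m).
#' @param z0m Roughness length for momentum (m).
#' @param psi_m Integrated stability correction for momentum (-).
#' @param constants Constants list, see [flux_constants()].
#' @return Wind speed at height `z` (m s-1).
#' @export
wind_profile <- function(z, ustar, d, z0m, psi_m = 0,
                         constants = flux_constants()) {
  below <- !is.na(z) & !is.na(d) & !is.na(z0m) & z < d + z0m
  if (any(below)) warning("z below d + z0m: wind speed set to missing")
  u <- (ustar / constants$k) * (log((z - d) / z0m) - psi_m)
  u[below] <- NA_real_
  u
}

#' Aerodynamic conductance to momentum transfer
#'
#' `Gam_from_ustar` uses the flux-variance form `Gam = ustar^2 / u`, which
#' accounts for atmospheric stability implicitly; `Gam_from_profile` uses
#' the stability-corrected logarithmic profile
#' `Gam = k * ustar / (ln((zr - d)/z0m) - psi_h)`.
#'
#' @param ustar Friction velocity (m s-1).
#' @param u Wind speed at reference height (m s-1).
#' @param zr,d,z0m Heights (m), profile form.
#' @param psi_h Integrated stability correction for heat (-), profile form.
#' @param constants Constants list, see [flux_constants()].
#' @return Conductance to momentum transfer (m s-1).
#' @examples
#' Gam_from_ustar(0.3, 2)  # 0.045
#' @export
Gam_from_ustar <- function(ustar, u) {
  ifelse(u <= 0, NA_real_, ustar^2 / u)
}

#' @rdname Gam_from_ustar
#' @export
Gam_from_profile <- function(ustar, zr, d, z0m, psi_h = 0,
                             constants = flux_constants()) {
  denom <- log((zr - d) / z0m) - psi_h
  bad <- !is.na(denom) & denom <= 0
  if (any(bad)) warning("non-positive profile denominator: Gam set to missing")
  out <- constants$k * ustar / denom
  out[bad] <- NA_real_
  out
}

#' Canopy boundary layer conductance models
#'
#' Three models for the quasi-laminar (excess) boundary layer conductance to
#' heat transfer `Gbh`:
#' \describe{
#'   \item{`Gb_Thom`}{empirical relation with friction velocity only:
#'     `Gbh = ustar^0.67 / 6.2`.}
#'   \item{`Gb_Choudhury`}{canopy integration of a leaf boundary layer
#'     conductance, requiring wind speed at canopy top, leaf area index and
#'     leaf width; the within-canopy wind attenuation coefficient is modeled
#'     as `alpha = 4.39 - 3.97 * exp(-0.258 * LAI)` unless supplied.}
#'   \item{`Gb_Su`}{physically based model combining a foliage term (drag
#'     coefficient, heat transfer coefficient `Ct` from the leaf-scale
#'     Reynolds number) with a bare-soil inverse Stanton number
#'     `kBs = 2.46 * Re_star^0.25 - ln(7.4)` weighted by fractional
#'     vegetation cover `fc` (default `1 - exp(-LAI/2)`).}
#' }
#'
#' @param ustar Friction velocity (m s-1).
#' @param u_zh Wind speed at canopy height (m s-1).
#' @param LAI Leaf area index (-).
#' @param leafwidth Leaf width (m), Choudhury model.
#' @param alpha Within-canopy wind attenuation coefficient (-); modeled from
#'   LAI when `NULL`.
#' @param Dl Leaf characteristic dimension (m), Su model.
#' @param fc Fractional vegetation cover (0..1); `1 - exp(-LAI/2)` when
#'   `NULL`.
#' @param z0m Roughness length for momentum (m), Su model (roughness
#'   Reynolds number of the soil term).
#' @param Ta Air temperature (deg C), Su model.
#' @param p Atmospheric pressure (kPa), Su model.
#' @param N Number of leaf sides participating in heat transfer.
#' @param constants Constants list, see [flux_constants()].
#' @return Boundary layer conductance to heat transfer (m s-1).
#' @examples
#' Gb_Thom(1)  # 1/6.2
#' Gb_Choudhury(u_zh = 1, LAI = 5, leafwidth = 0.02)
#' @export
Gb_Thom <- function(ustar) {
  ustar^0.67 / 6.2
}

#' @rdname Gb_Thom
#' @export
Gb_Choudhury <- function(u_zh, LAI, leafwidth, alpha = NULL) {
  if (is.null(alpha)) alpha <- 4.39 - 3.97 * exp(-0.258 * LAI)
  LAI * (0.02 / alpha) * sqrt(u_zh / leafwidth) / (1 - exp(-alpha / 2))
}

#' @rdname Gb_Thom
#' @export
Gb_Su <- function(ustar, u_zh, LAI, Dl, fc = NULL, z0m, Ta, p, N = 2,
                  constants = flux_constants()) {
  if (is.null(fc)) fc <- 1 - exp(-LAI / 2)
  nu <- kinematic_viscosity(Ta, p, constants)
  Re_h <- Dl * u_zh / nu
  Ct <- constants$Pr^(-2 / 3) * Re_h^(-1 / 2) * N
  Re_star <- z0m * ustar / nu
  kBs <- 2.46 * Re_star^0.25 - log(7.4)
  kB <- constants$k * constants$Cd * fc^2 / (4 * Ct * ustar / u_zh) +
    kBs * (1 - fc)^2
  constants$k * ustar / kB
}

#' Excess resistance parameter and roughness length for heat
#'
#' `kB_inv` computes the dimensionless excess resistance parameter
#' `kB_h^-1 = k * ustar / Gbh`; `z0h_from_kB` converts it to the roughness
#' length for heat `z0h = z0m / exp(kB_h^-1)`.
#'
#' @param Gb Boundary layer conductance to heat (m s-1).
#' @param ustar Friction velocity (m s-1).
#' @param z0m Roughness length for momentum (m).
#' @param kB Excess resistance parameter (-).
#' @param constants Constants list, see [flux_constants()].
#' @return `kB_inv`: kB_h^-1 (-); `z0h_from_kB`: z0h (m).
#' @export
kB_inv <- function(Gb, ustar, constants = flux_constants()) {
  constants$k * ustar / Gb
}

#' @rdname kB_inv
#' @export
z0h_from_kB <- function(z0m, kB) {
  z0m / exp(kB)
}

#' Boundary layer conductance for other scalars
#'
#' Scales `Gbh` to another scalar via the Schmidt number:
#' `Gbx = Gbh / (Sc_x / Pr)^0.67`.
#'
#' @param Gb Boundary layer conductance to heat (m s-1).
#' @param Sc Schmidt number of the scalar (-).
#' @param constants Constants list, see [flux_constants()].
#' @return Boundary layer conductance for the scalar (m s-1).
#' @export
scale_Gb <- function(Gb, Sc, constants = flux_constants()) {
  Gb / (Sc / constants$Pr)^0.67
}

#' Bulk aerodynamic conductance
#'
#' Composes the aerodynamic conductance to heat and CO2 transfer from a
#' momentum transfer model and a canopy boundary layer model, per record of
#' a flux time series: `1/Gah = 1/Gam + 1/Gbh`.
#'
#' @param data Data frame with (at least) columns `ustar` and `u`; the
#'   profile and stability computations additionally use `Ta`, `p`, `H`,
#'   and (optionally) `q`.
#' @param zr Reference height (m).
#' @param zh Canopy height (m); needed whenever `d`/`z0m` are not given or
#'   wind speed at canopy top must be estimated.
#' @param d,z0m Displacement height and momentum roughness length (m);
#'   estimated as `0.7 zh` and `0.1 zh` when `NULL`.
#' @param LAI Leaf area index (-), Choudhury and Su models.
#' @param Dl Leaf characteristic dimension / leaf width (m).
#' @param fc Fractional vegetation cover (0..1), Su model.
#' @param Gb_model Boundary layer model: `"Thom"`, `"Choudhury"`, `"Su"`, or
#'   `"constant_kB"` (user-supplied `kB`).
#' @param Gam_model Momentum transfer model: `"ustar"` (flux-variance) or
#'   `"profile"` (stability-corrected log profile).
#' @param stability_formulation See [stability_correction()].
#' @param kB User-supplied kB_h^-1 for `Gb_model = "constant_kB"`.
#' @param extra_Sc Optional named numeric vector of additional Schmidt
#'   numbers; one extra `Gb_<name>`/`Ga_<name>` column pair per entry.
#' @param zeta_limits Clamp applied to `zeta` before evaluating the psi
#'   functions, guarding against numerical blow-up in extreme records.
#' @param constants Constants list, see [flux_constants()].
#'
#' @return A data.frame with one row per record: conductances `Gam`, `Gbh`,
#'   `Gah`, `Gbc`, `Gac` (m s-1), resistances `Ram`, `Rbh`, `Rah`, `Rbc`,
#'   `Rac` (s m-1), `kB_h` (-), `zeta` (-), `L` (m), `psi_h`, `psi_m` (-),
#'   and `z0h` (m, when `z0m` is known).
#' @export
aerodynamic_conductance <- function(data, zr, zh = NULL, d = NULL, z0m = NULL,
                                    LAI = NULL, Dl = NULL, fc = NULL,
                                    Gb_model = c("Thom", "Choudhury", "Su",
                                                 "constant_kB"),
                                    Gam_model = c("ustar", "profile"),
                                    stability_formulation = "Dyer_1970",
                                    kB = NULL, extra_Sc = NULL,
                                    zeta_limits = c(-15, 15),
                                    constants = flux_constants()) {
  Gb_model <- match.arg(Gb_model)
  Gam_model <- match.arg(Gam_model)
  .check_columns(data, c("ustar", "u"))
  n <- nrow(data)

  need_geom <- Gam_model == "profile" || Gb_model %in% c("Choudhury", "Su")
  if (need_geom) {
    if (is.null(d) || is.null(z0m)) {
      if (is.null(zh)) stop("zh required to estimate d/z0m")
      rp <- roughness_parameters("canopy_height", zh = zh)
      if (is.null(d)) d <- rp$d
      if (is.null(z0m)) z0m <- rp$z0m
    }
  }

  # stability: needed for the profile Gam and for wind speed at canopy top
  zeta <- rep(NA_real_, n); L <- rep(NA_real_, n)
  psi_h <- rep(0, n); psi_m <- rep(0, n)
  if (need_geom) {
    .check_columns(data, c("Ta", "p", "H"))
    q <- if ("q" %in% names(data)) data$q else 0
    st <- stability_parameter(zr, d, data$ustar, data$H, data$Ta, q, data$p,
                              constants)
    zeta <- st$zeta; L <- st$L
    psi <- stability_correction(pmin(pmax(zeta, zeta_limits[1]),
                                     zeta_limits[2]),
                                stability_formulation)
    psi_h <- psi$psi_h; psi_m <- psi$psi_m
  }

  Gam <- switch(Gam_model,
                ustar = Gam_from_ustar(data$ustar, data$u),
                profile = Gam_from_profile(data$ustar, zr, d, z0m, psi_h,
                                           constants))

  Gbh <- switch(Gb_model,
    Thom = Gb_Thom(data$ustar),
    Choudhury = {
      if (is.null(LAI) || is.null(Dl))
        stop("Choudhury model requires LAI and Dl (leaf width)")
      u_zh <- wind_profile(zh, data$ustar, d, z0m, psi_m, constants)
      Gb_Choudhury(u_zh, LAI, Dl)
    },
    Su = {
      if (is.null(LAI) || is.null(Dl))
        stop("Su model requires LAI and Dl")
      .check_columns(data, c("Ta", "p"))
      u_zh <- wind_profile(zh, data$ustar, d, z0m, psi_m, constants)
      Gb_Su(data$ustar, u_zh, LAI, Dl, fc, z0m, data$Ta, data$p,
            constants = constants)
    },
    constant_kB = {
      if (is.null(kB)) stop("constant_kB model requires kB")
      constants$k * data$ustar / kB
    })

  kB_h <- kB_inv(Gbh, data$ustar, constants)
  Gbc <- scale_Gb(Gbh, constants$Sc_CO2, constants)
  Gah <- 1 / (1 / Gam + 1 / Gbh)
  Gac <- 1 / (1 / Gam + 1 / Gbc)

  out <- data.frame(
    Gam = Gam, Gbh = Gbh, Gah = Gah, Gbc = Gbc, Gac = Gac,
    Ram = 1 / Gam, Rbh = 1 / Gbh, Rah = 1 / Gah, Rbc = 1 / Gbc,
    Rac = 1 / Gac,
    kB_h = kB_h, zeta = zeta, L = L, psi_h = psi_h, psi_m = psi_m,
    z0h = if (!is.null(z0m)) z0h_from_kB(z0m, kB_h) else NA_real_
  )
  if (!is.null(extra_Sc)) {
    if (is.null(names(extra_Sc)) || any(names(extra_Sc) == ""))
      stop("extra_Sc must be a named numeric vector")
    for (nm in names(extra_Sc)) {
      Gbx <- scale_Gb(Gbh, extra_Sc[[nm]], constants)
      out[[paste0("Gb_", nm)]] <- Gbx
      out[[paste0("Ga_", nm)]] <- 1 / (1 / Gam + 1 / Gbx)
    }
  }
  out
}
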