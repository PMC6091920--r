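# Forward big-leaf generator: met + flux series from known parameters, so
# every inversion and fit in the package can be verified end-to-end.

#' Configuration for the synthetic flux generator
#'
#' Collects the generating parameters of [synthetic_fluxes()]. Defaults
#' describe a closed temperate forest canopy in the growing season with a
#' 12-hour light period, measured half-hourly a few meters above the
#' canopy.
#'
#' @param n_days Number of simulated days.
#' @param dt_mins Time step (minutes).
#' @param zr,zh Reference and canopy height (m); `zr > zh` required.
#' @param LAI Leaf area index (-).
#' @param Dl Leaf characteristic dimension (m).
#' @param frac_d,frac_z0m Roughness fractions of canopy height, giving the
#'   true `d` and `z0m` of the simulated wind profile.
#' @param SW_max Clear-sky noon shortwave radiation (W m-2).
#' @param Rn_frac,Rn_offset Net radiation model `Rn = Rn_frac * SW_in -
#'   Rn_offset` (W m-2).
#' @param Ta_mean,Ta_amp Daily mean and diurnal amplitude of air
#'   temperature (deg C).
#' @param rH_night Nighttime relative humidity (0..1) setting the daily
#'   vapor pressure level (VPD follows the temperature cycle).
#' @param u_min,u_amp Nighttime wind speed and diurnal wind amplitude
#'   (m s-1).
#' @param p Atmospheric pressure (kPa).
#' @param Ca Ambient CO2 concentration (umol mol-1).
#' @param G0,G1 True minimum conductance (mol m-2 s-1) and stomatal slope
#'   (kPa^0.5) of the unified stomatal optimization model generating
#'   surface conductance.
#' @param alpha,GPP_ref,Reco True light-response parameters: initial slope
#'   (umol CO2 per umol quanta), GPP at `PPFD_ref` (umol m-2 s-1), and
#'   ecosystem respiration (umol m-2 s-1).
#' @param PPFD_ref Reference PPFD of the light response (umol m-2 s-1).
#' @param closure Energy-balance closure factor (0..1]; the turbulent
#'   fluxes LE and H are scaled by it after the energy balance is formed,
#'   1 = exactly closed.
#' @param noise_flux Multiplicative lognormal noise level (sdlog) applied
#'   to LE, H, NEE and GPP; the lognormal is mean-one
#'   (`meanlog = -sdlog^2/2`). 0 disables.
#' @param noise_met Additive Gaussian noise s.d. on Ta (deg C) and
#'   relative noise on u; 0 disables.
#' @param rain_every_days Insert a midnight rain event every this many
#'   days (`0` disables).
#' @param rain_mm Rain amount per event (mm).
#' @param emissivity Surface longwave emissivity used for the simulated
#'   radiation streams.
#' @param start Start timestamp (parsed as UTC).
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_days = 105, dt_mins = 30,
                         zr = 30, zh = 20, LAI = 5, Dl = 0.02,
                         frac_d = 0.7, frac_z0m = 0.1,
                         SW_max = 800, Rn_frac = 0.85, Rn_offset = 40,
                         Ta_mean = 18, Ta_amp = 5, rH_night = 0.95,
                         u_min = 1, u_amp = 2, p = 101.325, Ca = 400,
                         G0 = 0, G1 = 2.0,
                         alpha = 0.05, GPP_ref = 30, Reco = 3,
                         PPFD_ref = 2000,
                         closure = 1,
                         noise_flux = 0.1, noise_met = 0,
                         rain_every_days = 11, rain_mm = 5,
                         emissivity = 0.98,
                         start = "2020-06-01") {
  cfg <- as.list(environment())
  if (cfg$zr <= cfg$zh) stop("zr must exceed zh")
  if (cfg$closure <= 0 || cfg$closure > 1) stop("closure must be in (0, 1]")
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a synthetic flux time series from a forward big-leaf model
#'
#' Builds a half-hourly met + flux table in the package's canonical layout
#' from known parameters, in this order: diurnal shortwave radiation,
#' temperature and VPD cycles; wind speed and friction velocity consistent
#' with the neutral logarithmic wind profile and the configured roughness;
#' GPP from the rectangular-hyperbola light response and `NEE = -GPP +
#' Reco`; surface conductance from the unified stomatal optimization model
#' with the prescribed slope; latent heat from the forward Penman-Monteith
#' equation with the matching aerodynamic conductance (momentum from the
#' profile, boundary layer from the friction-velocity model); and `H = (Rn
#' - G - S) - LE`, so the energy balance closes exactly unless a closure
#' factor below one is configured. Longwave streams consistent with the
#' implied aerodynamic surface temperature are added so the radiometric
#' inversion can be checked. Noise (seeded, reproducible) is applied last.
#'
#' @param config A [synth_config()] list.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A data.frame in canonical layout with attribute `"truth"`, a
#'   list carrying every generating parameter (including the derived `d`
#'   and `z0m`) and the noise-free `Gsw_mol` series.
#' @examples
#' d <- synthetic_fluxes(synth_config(n_days = 2, noise_flux = 0), seed = 1)
#' head(d)
#' @export
synthetic_fluxes <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  cst <- flux_constants()
  set.seed(seed)
  with(config, {
    steps_day <- 24 * 60 / dt_mins
    n <- n_days * steps_day
    timestamp <- seq(as.POSIXct(start, tz = "UTC"), by = dt_mins * 60,
                     length.out = n)
    hour <- (seq_len(n) - 1) %% steps_day * dt_mins / 60
    day <- rep(seq_len(n_days), each = steps_day)

    # radiation: clear-sky half-sine day, day-to-day cloudiness
    cloud <- stats::runif(n_days, 0.55, 1)[day]
    sun <- pmax(0, sin(pi * (hour - 6) / 12))
    SW_in <- SW_max * sun * cloud
    PPFD <- Rg_to_PPFD(SW_in, cst)
    Rn <- Rn_frac * SW_in - Rn_offset

    # temperature and humidity cycles
    day_dT <- stats::rnorm(n_days, 0, 1.5)[day]
    Ta <- Ta_mean + day_dT + Ta_amp * sin(2 * pi * (hour - 9) / 24)
    Ta_min <- Ta_mean + day_dT - Ta_amp
    e_a <- rH_night * esat_slope(Ta_min, constants = cst)$esat
    Da <- pmax(0.01, esat_slope(Ta, constants = cst)$esat - e_a)

    # wind: diurnal cycle; ustar from the neutral log profile (truth)
    d <- frac_d * zh
    z0m <- frac_z0m * zh
    u <- u_min + u_amp * sun
    ustar <- cst$k * u / log((zr - d) / z0m)

    # carbon: light response (truth), respiration constant
    GPP <- alpha * PPFD / (1 - PPFD / PPFD_ref + alpha * PPFD / GPP_ref)
    NEE <- -GPP + Reco

    # surface conductance from the stomatal model (truth, ambient D and C)
    Gsw_mol <- G0 + 1.6 * (1 + G1 / sqrt(Da)) * GPP / Ca
    Gsw_ms <- mol_to_ms(Gsw_mol, Ta, p, cst)

    # aerodynamic conductance chain used by the forward model
    Gam <- Gam_from_ustar(ustar, u)
    Gbh <- Gb_Thom(ustar)
    Gah <- 1 / (1 / Gam + 1 / Gbh)
    Gbc <- scale_Gb(Gbh, cst$Sc_CO2, cst)
    Gac_mol <- ms_to_mol(1 / (1 / Gam + 1 / Gbc), Ta, p, cst)

    LE <- penman_monteith(Rn, Ta = Ta, p = p, Da = Da, Gah = Gah,
                          Gsw = Gsw_ms, constants = cst)
    H <- (Rn - 0) - LE
    LE <- closure * LE
    H <- closure * H

    # longwave streams consistent with the aerodynamic surface temperature
    rho <- air_density(Ta, p, cst)
    Ts <- Ta + (H / closure) / (rho * Gah * cst$cp)
    LW_in <- 0.85 * cst$sigma * (Ta + cst$Kelvin)^4
    LW_out <- emissivity * cst$sigma * (Ts + cst$Kelvin)^4 +
      (1 - emissivity) * LW_in

    precip <- numeric(n)
    if (rain_every_days > 0) {
      rain_idx <- which(day %% rain_every_days == 0 & hour == 0)
      precip[rain_idx] <- rain_mm
    }

    if (noise_flux > 0) {
      eps <- function() stats::rlnorm(n, -noise_flux^2 / 2, noise_flux)
      LE <- LE * eps(); H <- H * eps()
      GPP <- GPP * eps()
      NEE <- -GPP + Reco * stats::rlnorm(n, -noise_flux^2 / 2, noise_flux)
    }
    if (noise_met > 0) {
      Ta <- Ta + stats::rnorm(n, 0, noise_met)
      u <- u * (1 + stats::rnorm(n, 0, noise_met / 10))
    }

    out <- data.frame(timestamp, Ta, p = p, Da, u, ustar, H, LE, Rn,
                      G = 0, S = 0, NEE, GPP, SW_in, LW_in, LW_out, PPFD,
                      precip, Ca = Ca)
    attr(out, "truth") <- list(
      zr = zr, zh = zh, LAI = LAI, Dl = Dl, d = d, z0m = z0m,
      G0 = G0, G1 = G1, alpha = alpha, GPP_ref = GPP_ref, Reco = Reco,
      PPFD_ref = PPFD_ref, closure = closure, Ca = Ca, p = p,
      emissivity = emissivity, noise_flux = noise_flux,
      noise_met = noise_met, Gsw_mol = Gsw_mol, Gah = Gah, Ts = Ts)
    out
  })
}
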