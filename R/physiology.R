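# Bulk physiological quantities: water-use efficiency metrics, stomatal
# slope and sensitivity fits, intercellular CO2, canopy photosynthetic
# capacity, light response, light-use efficiency.

#' Water-use efficiency metrics
#'
#' Computes ecosystem water-use efficiency (`WUE = GPP/ET`), inherent WUE
#' (`IWUE = GPP * Da / ET`), and underlying WUE
#' (`uWUE = GPP * sqrt(Da) / ET`), with GPP converted to g C and ET in kg
#' water, i.e. g C (kg H2O)-1 (times kPa or kPa^0.5).
#'
#' @param GPP Gross primary productivity (umol CO2 m-2 s-1).
#' @param Da Vapor pressure deficit (kPa).
#' @param Ta Air temperature (deg C), used when ET is derived from LE.
#' @param ET Evapotranspiration (kg m-2 s-1); non-positive values propagate
#'   as missing.
#' @param LE Latent heat flux (W m-2), alternative to `ET`.
#' @param aggregate Summary function applied over records (default
#'   [stats::median]); `NULL` returns the per-record data.frame.
#' @param constants Constants list, see [flux_constants()].
#' @return Named vector `c(WUE, IWUE, uWUE)` of aggregated metrics, or a
#'   per-record data.frame when `aggregate = NULL`.
#' @export
wue_metrics <- function(GPP, Da, Ta = NULL, ET = NULL, LE = NULL,
                        aggregate = stats::median,
                        constants = flux_constants()) {
  if (is.null(ET)) {
    if (is.null(LE) || is.null(Ta))
      stop("provide ET, or LE together with Ta")
    ET <- LE_to_ET(LE, Ta)
  }
  ET <- ifelse(ET <= 0, NA_real_, ET)
  gC <- GPP * 1e-06 * constants$Mc   # g C m-2 s-1
  out <- data.frame(WUE = gC / ET,
                    IWUE = gC * Da / ET,
                    uWUE = gC * sqrt(Da) / ET)
  if (is.null(aggregate)) return(out)
  vapply(out, function(x) aggregate(x[is.finite(x)]), numeric(1))
}

#' Stomatal slope parameter at ecosystem level
#'
#' Fits a stomatal conductance-photosynthesis coupling model to derived
#' surface conductance by nonlinear least squares (Levenberg-Marquardt) and
#' returns the slope parameter G1 (and, unless fixed, the minimum
#' conductance G0).
#'
#' Models:
#' \describe{
#'   \item{USO}{unified stomatal optimization,
#'     `Gsw = G0 + 1.6 * (1 + G1/sqrt(D)) * GPP / C`; G1 in kPa^0.5.}
#'   \item{BallBerry}{`Gsw = G0 + G1 * GPP * rH / C`; G1 dimensionless.}
#'   \item{Leuning}{`Gsw = G0 + G1 * GPP / ((C - Gamma) * (1 + D/D0))`;
#'     G1 dimensionless, `D0` (kPa) fitted unless fixed.}
#' }
#' `D` and `C` may be the big-leaf surface values (`Ds`, `Cs`, see
#' [surface_conditions()]) or the measured ambient values (`Da`, `Ca`).
#'
#' @param Gsw Surface conductance to water vapor (mol m-2 s-1).
#' @param GPP Gross primary productivity (umol CO2 m-2 s-1).
#' @param C CO2 concentration at the surface or in the air (umol mol-1).
#' @param D Vapor pressure deficit at the surface or in the air (kPa);
#'   non-positive values are excluded.
#' @param rH Relative humidity (0..1), Ball-Berry model.
#' @param model `"USO"` (default), `"BallBerry"`, or `"Leuning"`.
#' @param g0 `"free"` to estimate the intercept, or a fixed numeric value
#'   (e.g. 0).
#' @param Gamma CO2 compensation point (umol mol-1), Leuning model.
#' @param D0 VPD sensitivity parameter (kPa), Leuning model; fitted when
#'   `NULL`.
#' @param min_n Minimum number of complete records required (default 20).
#'
#' @return An object of class `"fluxleaf_fit"`: a list with `model`,
#'   `coefficients` (named vector), `se`, `n_used`, and the underlying
#'   `nls` fit.
#' @examples
#' set.seed(1)
#' D <- runif(100, 0.5, 3); GPP <- runif(100, 5, 25)
#' Gsw <- 1.6 * (1 + 2 / sqrt(D)) * GPP / 400
#' stomatal_slope(Gsw, GPP, C = 400, D = D, g0 = 0)
#' @export
stomatal_slope <- function(Gsw, GPP, C, D = NULL, rH = NULL,
                           model = c("USO", "BallBerry", "Leuning"),
                           g0 = "free", Gamma = 50, D0 = NULL, min_n = 20) {
  model <- match.arg(model)
  n <- length(Gsw)
  df <- data.frame(Gsw = Gsw, GPP = GPP,
                   C = rep_len(C, n),
                   D = if (is.null(D)) NA_real_ else rep_len(D, n),
                   rH = if (is.null(rH)) NA_real_ else rep_len(rH, n))
  if (model %in% c("USO", "Leuning")) {
    if (is.null(D)) stop(model, " model requires D")
    df <- df[!is.na(df$D) & df$D > 0, ]
  }
  if (model == "BallBerry") {
    if (is.null(rH)) stop("BallBerry model requires rH")
    df <- df[!is.na(df$rH), ]
  }
  df <- df[stats::complete.cases(df[c("Gsw", "GPP", "C")]), ]
  if (nrow(df) < min_n)
    stop("stomatal_slope: ", nrow(df), " usable records, need >= ", min_n)

  free_g0 <- identical(g0, "free")
  if (!free_g0) df$g0_fix <- g0

  fmla <- switch(model,
    USO = if (free_g0)
      Gsw ~ G0 + 1.6 * (1 + G1 / sqrt(D)) * GPP / C
    else
      Gsw ~ g0_fix + 1.6 * (1 + G1 / sqrt(D)) * GPP / C,
    BallBerry = if (free_g0)
      Gsw ~ G0 + G1 * GPP * rH / C
    else
      Gsw ~ g0_fix + G1 * GPP * rH / C,
    Leuning = {
      rhs <- if (is.null(D0))
        "G1 * GPP / ((C - Gamma) * (1 + D / D0))"
      else
        sprintf("G1 * GPP / ((C - Gamma) * (1 + D / %.10g))", D0)
      stats::as.formula(paste("Gsw ~", if (free_g0) "G0 +" else "g0_fix +",
                              rhs))
    })

  start <- list(G1 = switch(model, USO = 3, BallBerry = 9, Leuning = 7))
  if (free_g0) start$G0 <- 0
  if (model == "Leuning" && is.null(D0)) start$D0 <- 1.5
  df$Gamma <- Gamma

  fit <- minpack.lm::nlsLM(fmla, data = df, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  if (!free_g0) {
    cf <- c(cf, G0 = unname(g0))
    se <- c(se, G0 = NA_real_)
  }
  structure(list(model = model, coefficients = cf, se = se,
                 n_used = nrow(df), fit = fit),
            class = "fluxleaf_fit")
}

#' @export
print.fluxleaf_fit <- function(x, ...) {
  cat("model:", x$model, " (n =", x$n_used, ")\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.fluxleaf_fit <- function(object, ...) object$coefficients

#' Stomatal sensitivity to vapor pressure deficit
#'
#' Fits `Gsw = -m * ln(D) + b` by least squares; `b` is the reference
#' conductance at `D = 1` kPa and `m` the sensitivity.
#'
#' @param Gsw Surface conductance to water vapor (mol m-2 s-1).
#' @param D Vapor pressure deficit (kPa), surface or ambient; must be
#'   positive.
#' @param min_n Minimum number of complete records (default 20).
#' @return An object of class `"fluxleaf_fit"` with coefficients `m`
#'   (mol m-2 s-1 ln(kPa)-1) and `b` (mol m-2 s-1).
#' @export
stomatal_sensitivity <- function(Gsw, D, min_n = 20) {
  ok <- !is.na(Gsw) & !is.na(D) & D > 0
  if (sum(ok) < min_n)
    stop("stomatal_sensitivity: ", sum(ok), " usable records, need >= ",
         min_n)
  fit <- stats::lm(Gsw[ok] ~ log(D[ok]))
  cf <- c(m = -unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]))
  se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
  structure(list(model = "log_sensitivity", coefficients = cf,
                 se = c(m = unname(se[2]), b = unname(se[1])),
                 n_used = sum(ok), fit = fit),
            class = "fluxleaf_fit")
}

#' Bulk intercellular CO2 concentration
#'
#' Fick's-law inversion `Ci = Cs - GPP / Gsc` with the surface conductance
#' to CO2 `Gsc = Gsw / 1.6`.
#'
#' @param Cs CO2 concentration at the big-leaf surface (or ambient)
#'   (umol mol-1).
#' @param GPP Gross primary productivity (umol CO2 m-2 s-1).
#' @param Gsw Surface conductance to water vapor (mol m-2 s-1);
#'   non-positive values propagate as missing.
#' @param constants Constants list, see [flux_constants()].
#' @return Bulk intercellular CO2 concentration (umol mol-1).
#' @export
intercellular_CO2 <- function(Cs, GPP, Gsw, constants = flux_constants()) {
  Gsc <- ifelse(Gsw <= 0, NA_real_, Gsw / constants$DwDc)
  Cs - GPP / Gsc
}

# Arrhenius-type temperature scaling of a kinetic constant
.arrhenius <- function(TaK, Ha, Tref = 298.15, Rgas = 8.31451) {
  exp(Ha * (TaK - Tref) / (Tref * Rgas * TaK))
}

# Peaked (modified) Arrhenius factor normalizing a rate at TaK to 1 at Tref
.peaked_arrhenius <- function(TaK, Ha, Hd, dS, Tref = 298.15,
                              Rgas = 8.31451) {
  .arrhenius(TaK, Ha, Tref, Rgas) *
    (1 + exp((Tref * dS - Hd) / (Tref * Rgas))) /
    (1 + exp((TaK * dS - Hd) / (TaK * Rgas)))
}

#' Canopy photosynthetic capacity
#'
#' Estimates bulk canopy maximum carboxylation rate (Vcmax) and maximum
#' electron transport rate (Jmax) by inverting the Farquhar model per
#' record and aggregating with the median.
#'
#' Records at high light (`PPFD >= PPFD_c`) are treated as Rubisco-limited:
#' `Vcmax = GPP * (Ci + Kc * (1 + Oi/Ko)) / (Ci - Gamma_star)`.
#' Records at low light (`PPFD <= PPFD_j`) are treated as RuBP-regeneration
#' limited: `J = GPP * (4 Ci + 8 Gamma_star) / (Ci - Gamma_star)`, and Jmax
#' follows from the non-rectangular hyperbola of the light dependence of J
#' by exact inversion, `Jmax = J * (APPFD - Theta * J) / (APPFD - J)` with
#' `APPFD = f_APPFD * PPFD` (flux absorbed by photosystem II). Records with
#' `Ci <= Gamma_star` or `J >= APPFD` are excluded and counted. Per-record
#' values are normalized to 25 deg C with a peaked (modified) Arrhenius
#' function before taking the median.
#'
#' Kinetic constants and activation energies default to Bernacchi-type
#' values with a peaked-Arrhenius normalization (entropy term `dS`,
#' deactivation energy `Hd`); all are exposed via `kinetics` and echoed in
#' the result.
#'
#' @param GPP Gross primary productivity (umol CO2 m-2 s-1).
#' @param Ci Bulk intercellular CO2 concentration (umol mol-1).
#' @param Ta Air temperature (deg C).
#' @param PPFD Photosynthetic photon flux density (umol m-2 s-1).
#' @param PPFD_c Radiation threshold above which records are taken as
#'   Rubisco-limited (umol m-2 s-1).
#' @param PPFD_j Radiation threshold below which records are taken as
#'   RuBP-limited (umol m-2 s-1).
#' @param Theta Curvature of the J light response (-).
#' @param f_APPFD Fraction of PPFD absorbed by photosystem II (-).
#' @param kinetics Named list of kinetic constants at 25 deg C and
#'   activation energies (J mol-1): `Kc25` (umol mol-1), `Ko25`
#'   (mmol mol-1), `Gstar25` (umol mol-1), `Oi` (mol mol-1), `Ha_Kc`,
#'   `Ha_Ko`, `Ha_Gstar`, `Ha_Vcmax`, `Hd_Vcmax`, `dS_Vcmax`, `Ha_Jmax`,
#'   `Hd_Jmax`, `dS_Jmax`.
#' @param constants Constants list, see [flux_constants()].
#'
#' @return A list with `Vcmax25`, `Jmax25` (medians, umol m-2 s-1),
#'   `Vcmax`, `Jmax` (medians at ambient temperature), record counts
#'   `n_c`, `n_j`, exclusion counts, and the parameter set used.
#' @export
photosynthetic_capacity <- function(GPP, Ci, Ta, PPFD,
                                    PPFD_c = 1000, PPFD_j = 500,
                                    Theta = 0.85, f_APPFD = 0.8,
                                    kinetics = list(),
                                    constants = flux_constants()) {
  kin <- list(Kc25 = 404.9, Ko25 = 278.4, Gstar25 = 42.75, Oi = 0.21,
              Ha_Kc = 79430, Ha_Ko = 36380, Ha_Gstar = 37830,
              Ha_Vcmax = 65330, Hd_Vcmax = 200000, dS_Vcmax = 640,
              Ha_Jmax = 43900, Hd_Jmax = 200000, dS_Jmax = 640)
  kin[names(kinetics)] <- kinetics
  Rg <- constants$Rgas
  TaK <- Ta + constants$Kelvin

  Kc <- kin$Kc25 * .arrhenius(TaK, kin$Ha_Kc, Rgas = Rg)
  Ko <- kin$Ko25 * .arrhenius(TaK, kin$Ha_Ko, Rgas = Rg)
  Gstar <- kin$Gstar25 * .arrhenius(TaK, kin$Ha_Gstar, Rgas = Rg)
  Oi_mmol <- kin$Oi * 1000   # mol mol-1 -> mmol mol-1, same unit as Ko

  valid <- !is.na(GPP) & !is.na(Ci) & !is.na(TaK) & !is.na(PPFD)
  above_comp <- valid & Ci > Gstar
  n_excl_comp <- sum(valid & !(Ci > Gstar))

  # Rubisco-limited records
  rub <- above_comp & PPFD >= PPFD_c
  Vcmax_i <- GPP[rub] * (Ci[rub] + Kc[rub] * (1 + Oi_mmol / Ko[rub])) /
    (Ci[rub] - Gstar[rub])
  fV <- .peaked_arrhenius(TaK[rub], kin$Ha_Vcmax, kin$Hd_Vcmax,
                          kin$dS_Vcmax, Rgas = Rg)
  Vcmax25_i <- Vcmax_i / fV

  # RuBP-regeneration-limited records
  rubp <- above_comp & PPFD <= PPFD_j
  J_i <- GPP[rubp] * (4 * Ci[rubp] + 8 * Gstar[rubp]) /
    (Ci[rubp] - Gstar[rubp])
  APPFD <- f_APPFD * PPFD[rubp]
  physical <- J_i < APPFD & J_i > 0
  n_excl_J <- sum(!physical, na.rm = TRUE)
  J_i <- J_i[physical]; APPFD <- APPFD[physical]
  TaK_j <- TaK[rubp][physical]
  Jmax_i <- J_i * (APPFD - Theta * J_i) / (APPFD - J_i)
  fJ <- .peaked_arrhenius(TaK_j, kin$Ha_Jmax, kin$Hd_Jmax, kin$dS_Jmax,
                          Rgas = Rg)
  Jmax25_i <- Jmax_i / fJ

  med <- function(x) if (length(x)) stats::median(x, na.rm = TRUE) else NA_real_
  list(Vcmax25 = med(Vcmax25_i), Jmax25 = med(Jmax25_i),
       Vcmax = med(Vcmax_i), Jmax = med(Jmax_i), J = med(J_i),
       n_c = sum(rub), n_j = length(J_i),
       n_excluded_compensation = n_excl_comp,
       n_excluded_light = n_excl_J,
       Theta = Theta, f_APPFD = f_APPFD, kinetics = kin)
}

#' Electron transport rate from the light dependence of J
#'
#' Forward non-rectangular hyperbola
#' `J = (APPFD + Jmax - sqrt((APPFD + Jmax)^2 - 4 Theta APPFD Jmax)) /
#' (2 Theta)`; the exact inverse used in [photosynthetic_capacity()].
#'
#' @param APPFD Absorbed photon flux density at photosystem II
#'   (umol m-2 s-1).
#' @param Jmax Maximum electron transport rate (umol m-2 s-1).
#' @param Theta Curvature parameter (-).
#' @return Electron transport rate J (umol m-2 s-1).
#' @export
electron_transport <- function(APPFD, Jmax, Theta = 0.85) {
  (APPFD + Jmax - sqrt((APPFD + Jmax)^2 - 4 * Theta * APPFD * Jmax)) /
    (2 * Theta)
}

#' Ecosystem light response curve
#'
#' Fits the rectangular hyperbolic light response of net ecosystem exchange
#' `-NEE = alpha * PPFD / (1 - PPFD/PPFD_ref + alpha * PPFD / GPP_ref)
#' - Reco` by nonlinear least squares, with `PPFD_ref` fixed (default 2000
#' umol m-2 s-1, saturating light).
#'
#' @param NEE Net ecosystem exchange (umol CO2 m-2 s-1; uptake negative).
#' @param PPFD Photosynthetic photon flux density (umol m-2 s-1).
#' @param PPFD_ref Reference PPFD at which `GPP_ref` is evaluated
#'   (umol m-2 s-1).
#' @param min_n Minimum number of complete records (default 20).
#' @return An object of class `"fluxleaf_fit"` with coefficients `alpha`
#'   (umol CO2 per umol quanta), `GPP_ref` (umol m-2 s-1), and `Reco`
#'   (umol m-2 s-1).
#' @export
light_response <- function(NEE, PPFD, PPFD_ref = 2000, min_n = 20) {
  ok <- !is.na(NEE) & !is.na(PPFD) & PPFD >= 0
  if (sum(ok) < min_n)
    stop("light_response: ", sum(ok), " usable records, need >= ", min_n)
  df <- data.frame(negNEE = -NEE[ok], PPFD = PPFD[ok])
  Reco0 <- max(0.1, stats::median(df$negNEE[df$PPFD < 100]) * -1, na.rm = TRUE)
  if (!is.finite(Reco0)) Reco0 <- 1
  GPPref0 <- max(1, stats::quantile(df$negNEE, 0.98, na.rm = TRUE) + Reco0)
  fit <- minpack.lm::nlsLM(
    negNEE ~ alpha * PPFD / (1 - PPFD / PPFD_ref + alpha * PPFD / GPP_ref) -
      Reco,
    data = cbind(df, PPFD_ref = PPFD_ref),
    start = list(alpha = 0.05, GPP_ref = GPPref0, Reco = Reco0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  structure(list(model = "rectangular_hyperbola", coefficients = cf,
                 se = se, n_used = nrow(df), PPFD_ref = PPFD_ref, fit = fit),
            class = "fluxleaf_fit")
}

#' Light-use efficiency
#'
#' Ratio of cumulative GPP to cumulative PPFD over the non-missing paired
#' records, in mol CO2 (mol quanta)-1.
#'
#' @param GPP Gross primary productivity (umol CO2 m-2 s-1).
#' @param PPFD Photosynthetic photon flux density (umol m-2 s-1).
#' @return Light-use efficiency (mol mol-1).
#' @export
light_use_efficiency <- function(GPP, PPFD) {
  ok <- !is.na(GPP) & !is.na(PPFD)
  if (sum(PPFD[ok]) <= 0) stop("cumulative PPFD must be positive")
  sum(GPP[ok]) / sum(PPFD[ok])
}
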