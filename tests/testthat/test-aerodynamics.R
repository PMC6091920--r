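test_that("stability parameter has the neutral limit and correct sign", {
  st0 <- stability_parameter(30, 14, ustar = 0.4, H = 0, Ta = 20,
                             p = 101.325)
  expect_equal(st0$zeta, 0)
  up <- stability_parameter(30, 14, 0.4, H = 150, Ta = 20, p = 101.325)
  dn <- stability_parameter(30, 14, 0.4, H = -60, Ta = 20, p = 101.325)
  expect_true(up$zeta < 0 && dn$zeta > 0)
  # hand evaluation of L = -(ustar^3 rho cp Tv)/(k g H)
  st <- stability_parameter(zr = 20, d = 10, ustar = 0.3, H = 200,
                            Ta = 25, q = 0.01, p = 101.325)
  expect_equal(st$L, -11.977, tolerance = 1e-3)
  expect_equal(st$zeta, -0.8349, tolerance = 1e-3)
  expect_true(is.na(stability_parameter(20, 10, 0, 100, 20, 0, 100)$zeta))
})

test_that("stability corrections match their published forms", {
  expect_equal(stability_correction(0), data.frame(psi_h = 0, psi_m = 0))
  psi <- stability_correction(-0.1)
  expect_equal(psi$psi_h, 0.53427, tolerance = 1e-4)
  expect_equal(psi$psi_m, 0.28359, tolerance = 1e-4)
  expect_equal(stability_correction(0.1)$psi_h, -0.5)
  bs <- stability_correction(c(-0.1, 0.1), "Businger_1971")
  expect_true(bs$psi_h[1] > 0)
  expect_equal(bs$psi_h[2], -0.78)
  expect_equal(bs$psi_m[2], -0.6)
  expect_error(stability_correction(0, "nope"))
})

test_that("roughness parameters reproduce canopy-height fractions", {
  rp <- roughness_parameters("canopy_height", zh = 26.5)
  expect_equal(rp$d, 18.55)
  expect_equal(rp$z0m, 2.65)
  expect_equal(roughness_parameters("canopy_height", zh = 0.5)$z0m, 0.05)
  rp2 <- roughness_parameters("canopy_height_LAI", zh = 26.5, LAI = 7.6)
  expect_true(rp2$d > 0 && rp2$d < 26.5 && rp2$z0m > 0)
  expect_error(roughness_parameters("canopy_height_LAI", zh = 5), "LAI")
  expect_error(roughness_parameters("wind_profile", zh = 5, zr = 10), "data")
})

test_that("wind-profile roughness inversion recovers the generating z0m", {
  d <- synthetic_fluxes(noiseless_config(), seed = 3)
  tr <- attr(d, "truth")
  rp <- roughness_parameters("wind_profile", zh = tr$zh, zr = tr$zr,
                             data = d, d_prescribed = tr$d,
                             stab_correction = FALSE)
  expect_equal(rp$z0m, tr$z0m, tolerance = 0.01)
})

test_that("logarithmic wind profile behaves at its anchor and above", {
  expect_equal(wind_profile(z = 11, ustar = 1, d = 10, z0m = 1), 0)
  expect_equal(wind_profile(z = 20, ustar = 0.5, d = 10, z0m = 1), 2.80803,
               tolerance = 1e-5)
  u <- wind_profile(seq(12, 40, 2), 0.5, 10, 1)
  expect_true(all(diff(u) > 0))
  expect_warning(ub <- wind_profile(10.5, 0.5, 10, 1), "below")
  expect_true(is.na(ub))
})

test_that("momentum conductances: flux form, profile form, and their
           neutral equivalence", {
  expect_equal(Gam_from_ustar(0.3, 2), 0.045)
  expect_equal(Gam_from_ustar(0, 2), 0)
  expect_equal(Gam_from_ustar(0.6, 2), 4 * Gam_from_ustar(0.3, 2))
  expect_true(is.na(Gam_from_ustar(0.3, 0)))
  expect_equal(Gam_from_profile(0.5, zr = 25, d = 5, z0m = 1), 0.068431,
               tolerance = 1e-4)
  expect_true(Gam_from_profile(0.5, 25, 5, 1, psi_h = 0.5) >
              Gam_from_profile(0.5, 25, 5, 1, psi_h = 0))
  # algebraic identity: with u generated from the neutral log profile,
  # ustar^2/u equals k*ustar/ln((zr-d)/z0m)
  ustar <- c(0.2, 0.45, 0.8)
  u <- wind_profile(z = 25, ustar, d = 5, z0m = 1)
  expect_equal(Gam_from_ustar(ustar, u),
               Gam_from_profile(ustar, 25, 5, 1), tolerance = 1e-10)
})

test_that("boundary layer conductance models match hand evaluations", {
  expect_equal(Gb_Thom(1), 1 / 6.2)
  expect_true(all(diff(Gb_Thom(c(0.1, 0.3, 0.6, 1.2))) > 0))
  expect_equal(Gb_Thom(1e-12), 0, tolerance = 1e-8)

  expect_equal(Gb_Choudhury(u_zh = 1, LAI = 5, leafwidth = 0.02), 0.26555,
               tolerance = 1e-4)
  expect_equal(Gb_Choudhury(0, 5, 0.02), 0)
  expect_equal(Gb_Choudhury(4, 5, 0.02), 2 * Gb_Choudhury(1, 5, 0.02),
               tolerance = 1e-12)

  # hand-chained evaluation with z0m = 1 m
  expect_equal(Gb_Su(ustar = 0.5, u_zh = 2, LAI = 3, Dl = 0.02, z0m = 1,
                     Ta = 20, p = 101.325), 0.079851, tolerance = 1e-4)
  # default vegetation fraction: fc(LAI = 2) = 1 - exp(-1)
  g_default <- Gb_Su(0.5, 2, LAI = 2, Dl = 0.02, z0m = 1, Ta = 20,
                     p = 101.325)
  g_explicit <- Gb_Su(0.5, 2, LAI = 2, Dl = 0.02, fc = 1 - exp(-1),
                      z0m = 1, Ta = 20, p = 101.325)
  expect_equal(g_default, g_explicit)
  # dense canopy: the bare-soil term vanishes as fc -> 1
  g_fc1 <- Gb_Su(0.5, 2, LAI = 3, Dl = 0.02, fc = 1, z0m = 1, Ta = 20,
                 p = 101.325)
  g_fc999 <- Gb_Su(0.5, 2, LAI = 3, Dl = 0.02, fc = 0.9999, z0m = 1,
                   Ta = 20, p = 101.325)
  expect_equal(g_fc1, g_fc999, tolerance = 1e-3)
})

test_that("excess resistance parameter and Schmidt-number scaling", {
  expect_equal(kB_inv(Gb_Thom(1), 1), 2.5418, tolerance = 1e-4)
  expect_equal(z0h_from_kB(0.5, 0), 0.5)
  ustar <- c(0.2, 0.5, 1)
  z0h <- z0h_from_kB(1, kB_inv(Gb_Thom(ustar), ustar))
  expect_true(all(z0h < 1))
  expect_equal(scale_Gb(0.2, Sc = flux_constants()$Pr), 0.2)
  expect_equal(scale_Gb(1, Sc = 1.07), 1 / 1.31627, tolerance = 1e-4)
  expect_true(scale_Gb(1, 1.5) < scale_Gb(1, 1.0))
})

test_that("aerodynamic_conductance composes the chain record-wise", {
  toy <- data.frame(ustar = c(0.25, 0.5, NA), u = c(1.5, 3, NA),
                    Ta = 20, p = 101.325, H = c(50, 150, NA))
  ac <- aerodynamic_conductance(toy, zr = 30, zh = 20,
                                Gb_model = "Thom", Gam_model = "ustar")
  # series-resistor identity at every record
  expect_equal(1 / ac$Gah, 1 / ac$Gam + 1 / ac$Gbh, tolerance = 1e-12)
  # brute-force chain for the first record
  Gam1 <- 0.25^2 / 1.5
  Gbh1 <- 0.25^0.67 / 6.2
  expect_equal(ac$Gah[1], 1 / (1 / Gam1 + 1 / Gbh1), tolerance = 1e-12)
  expect_equal(ac$Gbc[1], Gbh1 / (1.07 / 0.71)^0.67, tolerance = 1e-12)
  # all-missing input record stays missing
  expect_true(all(is.na(ac[3, c("Gam", "Gbh", "Gah", "Gac", "Gbc")])))
  # conductance/resistance duality and series ordering
  expect_equal(ac$Gah[1:2] * ac$Rah[1:2], c(1, 1))
  expect_true(all(ac$Gah[1:2] < ac$Gam[1:2]))
  expect_true(all(ac$Gah[1:2] < ac$Gbh[1:2]))
  expect_error(aerodynamic_conductance(data.frame(u = 1), zr = 30),
               "ustar")
})

test_that("leaf-aware models exceed the Thom model for a rough
           high-LAI canopy", {
  # spruce-forest-like setting: tall canopy, small needles, high LAI
  toy <- data.frame(ustar = 0.6, u = 3, Ta = 15, p = 101.325, H = 100)
  gb <- function(model) {
    aerodynamic_conductance(toy, zr = 42, zh = 26.5, LAI = 7.6,
                            Dl = 0.008, Gb_model = model,
                            Gam_model = "ustar")$Gbh
  }
  expect_true(gb("Choudhury") > gb("Thom"))
  expect_true(gb("Su") > gb("Thom"))
})

test_that("extra Schmidt numbers yield additional conductance columns", {
  toy <- data.frame(ustar = 0.4, u = 2.5, Ta = 18, p = 100, H = 80)
  ac <- aerodynamic_conductance(toy, zr = 30, zh = 20, Gb_model = "Thom",
                                Gam_model = "ustar",
                                extra_Sc = c(O3 = 1.05))
  expect_true(all(c("Gb_O3", "Ga_O3") %in% names(ac)))
  expect_equal(ac$Gb_O3, scale_Gb(ac$Gbh, 1.05), tolerance = 1e-12)
})
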