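test_that("Penman-Monteith inversion is the exact inverse of the forward
           equation", {
  set.seed(11)
  n <- 200
  Ta <- runif(n, 5, 35); p <- runif(n, 85, 102); Da <- runif(n, 0.1, 3)
  Gah <- runif(n, 0.02, 0.25); Gsw <- runif(n, 0.001, 0.03)
  Rn <- runif(n, 50, 700); G <- runif(n, -20, 60)
  LE <- penman_monteith(Rn, G, NULL, Ta, p, Da, Gah, Gsw)
  inv <- surface_conductance(Rn, G, NULL, LE, Da, Ta, p, Gah)
  expect_equal(inv$Gsw_ms, Gsw, tolerance = 1e-10)
})

test_that("surface conductance hand value, zero case, and flags", {
  gs <- surface_conductance(Rn = 400, LE = 200, Da = 1.5, Ta = 25,
                            p = 101.325, Gah = 0.1)
  expect_equal(gs$Gsw_ms, 6.6145e-3, tolerance = 1e-4)
  expect_equal(surface_conductance(Rn = 400, LE = 0, Da = 1.5, Ta = 25,
                                   p = 101.325, Gah = 0.1)$Gsw_ms, 0)
  neg <- surface_conductance(Rn = 400, LE = -40, Da = 1.5, Ta = 25,
                             p = 101.325, Gah = 0.1)
  expect_equal(neg$flag, "negative")
  expect_true(neg$Gsw_ms < 0)
})

test_that("flux-gradient conductance is the infinite-Gah limit form", {
  # forward: E_mol = Gs_mol * Da/p, LE = E_mol * Mw * lambda
  cst <- flux_constants()
  Gs_mol <- 0.3; Da <- 1.2; Ta <- 22; p <- 100
  LE <- Gs_mol * (Da / p) * cst$Mw * latent_heat_vaporization(Ta)
  fg <- surface_conductance(LE = LE, Da = Da, Ta = Ta, p = p,
                            method = "flux_gradient")
  expect_equal(fg$Gsw_mol, Gs_mol, tolerance = 1e-12)
})

test_that("longwave conductance follows its printed form", {
  expect_equal(longwave_conductance(25, LAI = 0), 0)
  expect_equal(longwave_conductance(25, LAI = 3), 0.0179473,
               tolerance = 1e-5)
  expect_equal(longwave_conductance(25, 6), 2 * longwave_conductance(25, 3),
               tolerance = 1e-12)
})

test_that("decoupling coefficient: limits, radiative degeneration,
           ordering", {
  Ta <- 25; p <- 101.325
  sg <- esat_slope(Ta)$delta / psychrometric_constant(Ta, p)
  om <- decoupling(Gsw = 0.01, Gah = 0.03, Ta, p)
  expect_equal(om, (sg + 1) / (sg + 1 + 3), tolerance = 1e-12)
  expect_true(decoupling(0.01, 10, Ta, p) < 0.01)          # Gah >> Gsw
  expect_true(decoupling(0.01, 1e-6, Ta, p) > 0.999)       # Gah -> 0
  # Martin form reduces exactly to Jarvis-McNaughton at Gr = 0
  expect_equal(decoupling(0.01, 0.03, Ta, p, "Martin", Gr = 0), om,
               tolerance = 1e-12)
  # radiative coupling lowers omega over a parameter grid
  grid <- expand.grid(Gsw = c(0.002, 0.01, 0.03),
                      Gah = c(0.02, 0.06, 0.2), Ta = c(10, 25))
  Gr <- longwave_conductance(grid$Ta, LAI = 4)
  oj <- decoupling(grid$Gsw, grid$Gah, grid$Ta, p)
  om2 <- decoupling(grid$Gsw, grid$Gah, grid$Ta, p, "Martin", Gr = Gr)
  expect_true(all(om2 < oj))
  expect_true(all(oj >= 0 & oj <= 1))
})

test_that("omega-weighted sum of equilibrium and imposed ET equals the
           forward Penman-Monteith flux", {
  set.seed(21)
  n <- 500
  Ta <- runif(n, 5, 35); p <- runif(n, 85, 102); Da <- runif(n, 0.05, 3)
  Gah <- runif(n, 0.01, 0.3); Gsw <- runif(n, 0.001, 0.03)
  Rn <- runif(n, 0, 700)
  comp <- equilibrium_imposed_ET(Rn, NULL, NULL, Ta, p, Da, Gsw)
  om <- decoupling(Gsw, Gah, Ta, p)
  LE_pm <- penman_monteith(Rn, NULL, NULL, Ta, p, Da, Gah, Gsw)
  expect_equal(om * comp$LE_eq + (1 - om) * comp$LE_imp, LE_pm,
               tolerance = 1e-9)
  expect_equal(equilibrium_imposed_ET(300, NULL, NULL, 20, 100, Da = 0,
                                      Gsw = 0.01)$LE_imp, 0)
  expect_equal(equilibrium_imposed_ET(0, NULL, NULL, 20, 100, 1,
                                      0.01)$LE_eq, 0)
})

test_that("potential ET: Priestley-Taylor hand value and PM limits", {
  expect_equal(potential_ET("PriestleyTaylor", Rn = 400, Ta = 25,
                            p = 101.325), 371.69, tolerance = 1e-3)
  expect_equal(potential_ET("PriestleyTaylor", Rn = 400, Ta = 25,
                            p = 101.325, alpha_PT = 2.52),
               2 * 371.688, tolerance = 1e-3)
  # PM form with huge reference conductance and Da = 0 approaches
  # equilibrium ET
  le_eq <- equilibrium_imposed_ET(400, NULL, NULL, 25, 101.325, 0,
                                  0.01)$LE_eq
  le_pm <- potential_ET("PenmanMonteith", Rn = 400, Ta = 25, p = 101.325,
                        Da = 0, Gah = 0.1, Gsw_ref = 1e9)
  expect_equal(le_pm, le_eq, tolerance = 1e-6)
})

test_that("energy closure: constructed slope and ratio, order invariance", {
  d <- synthetic_fluxes(noiseless_config(n_days = 5), seed = 2)
  ec <- energy_closure(d)
  expect_equal(ec$slope, 1, tolerance = 1e-9)
  expect_equal(ec$EBR, 1, tolerance = 1e-9)
  expect_equal(ec$intercept, 0, tolerance = 1e-7)
  d2 <- d
  d2$LE <- 0.8 * d$LE; d2$H <- 0.8 * d$H
  ec2 <- energy_closure(d2)
  expect_equal(ec2$slope, 0.8, tolerance = 1e-9)
  expect_equal(ec2$EBR, 0.8, tolerance = 1e-9)
  ec3 <- energy_closure(d2[sample(nrow(d2)), ])
  expect_equal(ec3$EBR, ec2$EBR, tolerance = 1e-12)
  expect_error(energy_closure(d[1, ]), "2")
})

test_that("biochemical energy and energy use efficiency", {
  expect_equal(biochemical_energy(0), 0)
  expect_equal(abs(biochemical_energy(-20)), 8.44)
  expect_equal(energy_use_efficiency(-20, Rn = 400), 8.44 / 400)
  expect_equal(energy_use_efficiency(-40, 400),
               2 * energy_use_efficiency(-20, 400))
  expect_true(is.na(energy_use_efficiency(-20, 0)))
})
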