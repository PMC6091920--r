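test_that("water-use efficiency metrics: units, unit-VPD identity,
           linearity", {
  # hand conversion: 10 umol CO2 = 10 * 12.011e-6 g C per m2 s
  w <- wue_metrics(GPP = 10, Da = 1.5, ET = 2e-5, aggregate = NULL)
  expect_equal(w$WUE, 6.0055, tolerance = 1e-4)
  w1 <- wue_metrics(GPP = 10, Da = 1, ET = 2e-5, aggregate = NULL)
  expect_equal(w1$WUE, w1$IWUE)
  expect_equal(w1$WUE, w1$uWUE)
  w2 <- wue_metrics(GPP = 20, Da = 1.5, ET = 2e-5, aggregate = NULL)
  expect_equal(unlist(w2), 2 * unlist(w), tolerance = 1e-12)
  expect_true(all(is.na(wue_metrics(10, 1, ET = -1, aggregate = NULL))))
  # LE route agrees with the explicit ET route
  wle <- wue_metrics(GPP = 10, Da = 1.5, Ta = 25,
                     LE = ET_to_LE(2e-5, 25), aggregate = NULL)
  expect_equal(wle$WUE, w$WUE, tolerance = 1e-12)
})

test_that("stomatal slope models recover generating parameters exactly on
           noise-free data", {
  set.seed(5)
  n <- 300
  D <- runif(n, 0.3, 3); GPP <- runif(n, 2, 30); C <- runif(n, 380, 420)
  Gsw_uso <- 1.6 * (1 + 2 / sqrt(D)) * GPP / C
  f <- stomatal_slope(Gsw_uso, GPP, C, D, g0 = 0)
  expect_equal(unname(coef(f)["G1"]), 2, tolerance = 1e-6)
  f2 <- stomatal_slope(0.04 + Gsw_uso, GPP, C, D)
  expect_equal(unname(coef(f2)["G1"]), 2, tolerance = 1e-6)
  expect_equal(unname(coef(f2)["G0"]), 0.04, tolerance = 1e-6)

  rH <- runif(n, 0.3, 0.9)
  Gsw_bb <- 0.01 + 9 * GPP * rH / C
  fb <- stomatal_slope(Gsw_bb, GPP, C, rH = rH, model = "BallBerry")
  expect_equal(unname(coef(fb)["G1"]), 9, tolerance = 1e-6)

  Gsw_leu <- 0.02 + 7 * GPP / ((C - 50) * (1 + D / 1.5))
  fl <- stomatal_slope(Gsw_leu, GPP, C, D, model = "Leuning", D0 = 1.5)
  expect_equal(unname(coef(fl)["G1"]), 7, tolerance = 1e-6)
  fl2 <- stomatal_slope(Gsw_leu, GPP, C, D, model = "Leuning")
  expect_equal(unname(coef(fl2)["D0"]), 1.5, tolerance = 1e-4)

  expect_error(stomatal_slope(Gsw_uso[1:5], GPP[1:5], C[1:5], D[1:5]),
               "usable records")
})

test_that("stomatal slope recovery under multiplicative noise", {
  set.seed(42)
  n <- 5000
  D <- runif(n, 0.3, 3); GPP <- runif(n, 2, 30)
  Gsw <- 1.6 * (1 + 2 / sqrt(D)) * GPP / 400
  Gsw_n <- Gsw * rlnorm(n, -0.005, 0.1)
  f <- stomatal_slope(Gsw_n, GPP, 400, D, g0 = 0)
  expect_equal(unname(coef(f)["G1"]), 2, tolerance = 0.02)
})

test_that("stomatal sensitivity fit: anchor at 1 kPa and noisy recovery", {
  set.seed(9)
  D <- runif(2000, 0.2, 4)
  Gsw <- -0.1 * log(D) + 0.3
  f0 <- stomatal_sensitivity(Gsw, D)
  expect_equal(unname(coef(f0)), c(0.1, 0.3), tolerance = 1e-9)
  # predicted conductance at D = 1 kPa is the intercept b
  expect_equal(-coef(f0)[["m"]] * log(1) + coef(f0)[["b"]], 0.3,
               tolerance = 1e-9)
  fn <- stomatal_sensitivity(Gsw * rlnorm(2000, -0.005, 0.1), D)
  expect_equal(unname(coef(fn)), c(0.1, 0.3), tolerance = 0.05)
  expect_error(stomatal_sensitivity(Gsw[1:3], D[1:3]), "usable records")
})

test_that("intercellular CO2 from Fick's law", {
  expect_equal(intercellular_CO2(Cs = 380, GPP = 0, Gsw = 0.3), 380)
  expect_equal(intercellular_CO2(380, 20, Gsw = 0.25 * 1.6), 300)
  set.seed(3)
  GPP <- runif(50, 1, 30); Gsw <- runif(50, 0.05, 0.5)
  expect_true(all(intercellular_CO2(400, GPP, Gsw) < 400))
  expect_true(is.na(intercellular_CO2(400, 10, 0)))
})

test_that("photosynthetic capacity: hand values at 25 degC and the
           electron-transport round trip", {
  # single Rubisco-limited record at the reference temperature
  pc <- photosynthetic_capacity(GPP = 20, Ci = 300, Ta = 25, PPFD = 1500)
  expect_equal(pc$Vcmax25, 78.548, tolerance = 1e-4)
  expect_equal(pc$Vcmax25, pc$Vcmax, tolerance = 1e-12)  # factor 1 at 25 C
  # single RuBP-limited record: J and its Jmax inversion
  pc2 <- photosynthetic_capacity(GPP = 15, Ci = 300, Ta = 25, PPFD = 500)
  expect_equal(pc2$J, 89.9125, tolerance = 1e-4)
  expect_equal(pc2$Jmax, 93.8233, tolerance = 1e-4)
  # closed-form inversion: forward light dependence returns J
  J <- electron_transport(APPFD = 640, Jmax = 92.1038, Theta = 0.85)
  expect_equal(J, 89.9, tolerance = 1e-4)
  Jmax_back <- J * (640 - 0.85 * J) / (640 - J)
  expect_equal(electron_transport(640, Jmax_back, 0.85), J,
               tolerance = 1e-9)
})

test_that("photosynthetic capacity excludes unphysical records and
           aggregates by median", {
  GPP <- c(20, 22, 18, 5, 15)
  Ci <- c(300, 310, 290, 30, 300)      # 4th below compensation point
  Ta <- rep(25, 5)
  PPFD <- c(1500, 1600, 1400, 1200, 500)
  pc <- photosynthetic_capacity(GPP, Ci, Ta, PPFD)
  expect_equal(pc$n_excluded_compensation, 1)
  expect_equal(pc$n_c, 3)
  expect_equal(pc$n_j, 1)
  # median over the three Rubisco-limited records
  each <- vapply(1:3, function(i)
    photosynthetic_capacity(GPP[i], Ci[i], Ta[i], PPFD[i])$Vcmax25,
    numeric(1))
  expect_equal(pc$Vcmax25, median(each), tolerance = 1e-12)
  # temperature normalization is the identity exactly at 25 degC
  pc25 <- photosynthetic_capacity(20, 300, 25, 1500)
  pc30 <- photosynthetic_capacity(20, 300, 30, 1500)
  expect_true(pc30$Vcmax25 < pc30$Vcmax)
  expect_equal(pc25$Vcmax25, pc25$Vcmax)
})

test_that("light response fit: dark limit, exact and noisy recovery", {
  set.seed(14)
  PPFD <- runif(3000, 0, 2200)
  PPFD[1:10] <- 0
  NEE <- -(0.05 * PPFD / (1 - PPFD / 2000 + 0.05 * PPFD / 30) - 3)
  f0 <- light_response(NEE, PPFD)
  expect_equal(unname(coef(f0)), c(0.05, 30, 3), tolerance = 1e-6)
  # fitted curve in darkness is -Reco
  expect_equal(unname(fitted(f0$fit)[1:10]), rep(-coef(f0)[["Reco"]], 10),
               tolerance = 1e-9)
  fn <- light_response(NEE * rlnorm(3000, -0.005, 0.1), PPFD)
  expect_equal(unname(coef(fn)), c(0.05, 30, 3), tolerance = 0.05)
  expect_error(light_response(NEE[1:4], PPFD[1:4]), "usable records")
})

test_that("light-use efficiency is a ratio of sums", {
  expect_equal(light_use_efficiency(GPP = rep(0, 10), PPFD = rep(500, 10)),
               0)
  PPFD <- runif(100, 100, 2000)
  expect_equal(light_use_efficiency(0.02 * PPFD, PPFD), 0.02,
               tolerance = 1e-12)
  o <- sample(100)
  expect_equal(light_use_efficiency(0.02 * PPFD[o], PPFD[o]), 0.02,
               tolerance = 1e-12)
  expect_error(light_use_efficiency(1, 0), "positive")
})
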