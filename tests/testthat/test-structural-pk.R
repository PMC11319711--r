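# Subject-level ODE engine: closed forms, conservation laws, and the
# independent deSolve cross-check.

test_that("with no dosing the central compartment decays monoexponentially", {
  s <- test_subject(Qc0 = 40)
  reg <- dosing_regimen(numeric(), numeric(), character())
  times <- seq(0, 60, by = 2)
  prof <- simulate_profile(s, reg, times)
  expected <- s$Qc0 / s$V * 1000 * exp(-(s$CL / s$V) * times)
  expect_equal(prof$conc, expected, tolerance = 1e-7)
})

test_that("a single PP1M dose is fully eliminated with AUC(inf) = Dose/CL", {
  s <- test_subject(Qc0 = 0.001)  # negligible initial burden
  D <- 150
  prof <- simulate_profile(s, single_pp1m(D), times = c(0, 3000),
                           full_state = TRUE)
  final <- prof[2, ]
  expect_equal(final$Qelim, D + s$Qc0, tolerance = 1e-4)
  # AUC in ng/mL*day; Dose/CL in mg/L*day needs the same unit factor
  expect_equal(final$AUCstate, (D + s$Qc0) / s$CL * 1000, tolerance = 1e-4)
})

test_that("a PP3M injection deposits f3 and (1 - f3) shares of the dose", {
  s <- test_subject(f3 = 0.3, Qc0 = 0.001)
  D <- 525
  prof <- simulate_profile(s, single_pp3m(D), times = 0, full_state = TRUE)
  expect_equal(prof$Qdepot_r3, s$f3 * D, tolerance = 1e-12)
  expect_equal(prof$Qdepot_s3, (1 - s$f3) * D, tolerance = 1e-12)
})

test_that("mass is conserved for random subjects and regimens", {
  set.seed(401)
  for (i in 1:20) {
    s <- random_subject()
    reg <- random_regimen()
    horizon <- max(reg$time) + 120
    prof <- simulate_profile(s, reg, seq(0, horizon, length.out = 25),
                             full_state = TRUE)
    err <- mass_balance_error(prof, s, reg)
    expect_lt(max(abs(err)), 1e-6)
  }
})

test_that("cumulative elimination and the AUC state are non-decreasing", {
  s <- test_subject()
  prof <- simulate_profile(s, pp_regimen(), seq(0, 476, by = 1),
                           full_state = TRUE)
  expect_true(all(diff(prof$Qelim) >= -1e-9))
  expect_true(all(diff(prof$AUCstate) >= -1e-9))
})

test_that("the PP1M-only model is dose-linear; the PP3M model is not", {
  s <- test_subject(Qc0 = 1e-6)
  times <- seq(1, 200, by = 7)
  reg1 <- dosing_regimen(c(0, 28, 56), 150, "PP1M")
  reg2 <- dosing_regimen(c(0, 28, 56), 300, "PP1M")
  c1 <- simulate_profile(s, reg1, times)$conc
  c2 <- simulate_profile(s, reg2, times)$conc
  expect_equal(c2, 2 * c1, tolerance = 1e-6)
  # the saturable slow depot must break linearity
  c3 <- simulate_profile(s, single_pp3m(262.5), times)$conc
  c4 <- simulate_profile(s, single_pp3m(525), times)$conc
  expect_gt(max(abs(c4 / c3 - 2)), 0.05)
})

test_that("successive PP3M injections superpose in the depot amounts", {
  s <- test_subject(f3 = 0.25, Qc0 = 0.001)
  reg <- dosing_regimen(c(0, 91), c(400, 525), "PP3M")
  eps <- 1e-9
  prof <- simulate_profile(s, reg, c(91 - eps, 91), full_state = TRUE)
  expect_equal(prof$Qdepot_r3[2] - prof$Qdepot_r3[1], s$f3 * 525,
               tolerance = 1e-7)
  expect_equal(prof$Qdepot_s3[2] - prof$Qdepot_s3[1], (1 - s$f3) * 525,
               tolerance = 1e-7)
})

test_that("the compiled integrator agrees with an independent deSolve solution", {
  skip_if_not_installed("deSolve")
  set.seed(402)
  for (i in 1:3) {
    s <- random_subject()
    times <- seq(0, 476, by = 7)
    mine <- simulate_profile(s, pp_regimen(), times, full_state = TRUE)
    ref <- desolve_profile(s, pp_regimen(), times)
    expect_equal(mine$conc, ref$conc, tolerance = 1e-6)
    expect_equal(mine$AUCstate, ref$AUCstate, tolerance = 1e-6)
  }
})

test_that("a constant profile yields cmax = c and auc = c * dt", {
  # near-zero clearance freezes the initial burden: concentration constant
  s <- test_subject(CL = 1e-8, Qc0 = 40)
  reg <- dosing_regimen(numeric(), numeric(), character())
  m <- exposure_model_integrated(s, reg, c(10, 30))
  c0 <- s$Qc0 / s$V * 1000
  expect_equal(m$cmax, c0, tolerance = 1e-7)
  expect_equal(m$auc, c0 * 20, tolerance = 1e-7)
})

test_that("the augmented-ODE AUC matches a dense trapezoid quadrature", {
  s <- test_subject()
  iv <- last_dosing_period(pp_regimen())
  m <- exposure_model_integrated(s, pp_regimen(), iv)
  grid <- seq(iv[1], iv[2], length.out = 10000)
  conc <- simulate_profile(s, pp_regimen(), grid)$conc
  trap <- sum(diff(grid) * (conc[-1] + conc[-length(conc)]) / 2)
  expect_equal(m$auc, trap, tolerance = 1e-4)
})

test_that("the 100-point Cmax grid is within 0.5% of a refined grid", {
  s <- test_subject()
  iv <- last_dosing_period(pp_regimen())
  m100 <- exposure_model_integrated(s, pp_regimen(), iv, n_grid = 100)
  m10k <- exposure_model_integrated(s, pp_regimen(), iv, n_grid = 10000)
  expect_lt(abs(m100$cmax / m10k$cmax - 1), 0.005)
})

test_that("invalid parameters, regimens and intervals are rejected", {
  expect_error(test_subject(f1 = 1.2), "strictly in")
  expect_error(test_subject(CL = -1), "positive")
  expect_error(test_subject(gamma = -0.5), "positive")
  expect_error(dosing_regimen(c(10, 10), 100, "PP3M"), "increasing")
  expect_error(dosing_regimen(0, -5, "PP3M"), "non-negative")
  expect_error(dosing_regimen(0, 100, "oral"), "PP1M")
  expect_error(exposure_model_integrated(test_subject(), pp_regimen(),
                                         c(100, 50)), "interval")
  expect_error(exposure_model_integrated(test_subject(), pp_regimen(),
                                         c(-10, 50)), "horizon")
})
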