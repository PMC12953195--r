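protocol <- itc_protocol()

test_that("cell concentrations follow the overflow dilution product", {
  cc <- cell_concentrations(protocol)
  expect_equal(cc$lt[1], 100 * (2 / 200.3), tolerance = 1e-9)
  expect_equal(cc$pt[1], 10 * (1 - 2 / 200.3), tolerance = 1e-9)
  expect_equal(cc$pt[19], 10 * (1 - 2 / 200.3)^19, tolerance = 1e-9)
  expect_equal(cc$lt[19], 100 * (1 - (1 - 2 / 200.3)^19), tolerance = 1e-9)
  expect_equal(cc$molar_ratio[19], 2.10, tolerance = 0.005)
  # dilution monotonicity
  expect_true(all(diff(cc$pt) < 0))
  expect_true(all(diff(cc$lt) > 0))
  expect_true(all(diff(cc$molar_ratio) > 0))
  expect_error(cell_concentrations(protocol, 20), "out of range")
})

test_that("closed-form complex concentration matches the iterative solver", {
  expect_equal(complex_concentration(10, 0, 1e5), 0)
  expect_equal(complex_concentration(10, 5, 1e5, n = 1), 2.192, tolerance = 1e-3)
  # stoichiometric limit at very tight binding
  expect_equal(complex_concentration(10, 5, 1e12), 5, tolerance = 1e-4)
  expect_equal(complex_concentration(4, 50, 1e12, n = 0.8), 3.2, tolerance = 1e-4)
  set.seed(7)
  for (k in 1:50) {
    pt <- runif(1, 1, 50); lt <- runif(1, 0, 60)
    ka <- 10^runif(1, 3, 8); n <- runif(1, 0.5, 1.5)
    expect_equal(complex_concentration(pt, lt, ka, n),
                 oracle_complex_uM(pt, lt, ka, n), tolerance = 1e-10)
  }
})

test_that("mass conservation bounds the complex for arbitrary parameters", {
  set.seed(13)
  for (k in 1:100) {
    pt <- runif(1, 0.1, 100); lt <- runif(1, 0, 150)
    ka <- 10^runif(1, 2, 10); n <- runif(1, 0.3, 2)
    pl <- complex_concentration(pt, lt, ka, n)
    expect_gte(pl, 0)
    expect_lte(pl, min(n * pt, lt) + 1e-9)
  }
})

test_that("injection heats reduce to known limits", {
  # athermal titration returns only the background heat
  q0 <- injection_heats(protocol, ka = 1e5, dh = 0, n = 1, qd = 0.37)
  expect_true(all(abs(q0$heat - 0.37) < 1e-12))
  # vanishing affinity also returns only the background heat
  qk <- injection_heats(protocol, ka = 1e-3, dh = 20, n = 1, qd = 0.2)
  expect_true(all(abs(qk$heat - 0.2) < 1e-4))
  # tight binding with protein excess: first normalized heat equals dH
  qt <- injection_heats(protocol, ka = 1e12, dh = 27.7, n = 1, qd = 0)
  expect_equal(qt$heat[1], 27.7, tolerance = 1e-4)
})

test_that("the injection forward model agrees with the brute-force simulator", {
  q_model <- injection_heats(protocol, ka = 1e5, dh = 27.7, n = 0.85, qd = 0.5)
  q_oracle <- oracle_injection_heats(protocol, ka = 1e5, dh = 27.7, n = 0.85, qd = 0.5)
  expect_lt(max(abs(q_model$heat - q_oracle)), 1e-8)
})

test_that("isotherm fitting recovers all four parameters from noiseless data", {
  iso <- simulate_itc(protocol, ka = 1e5, dh = 27.7, n = 0.85, qd = 0.5, sigma = 0)
  fit <- fit_isotherm(iso, protocol)
  expect_lt(abs(fit$ka - 1e5) / 1e5, 1e-3)
  expect_lt(abs(fit$dh - 27.7) / 27.7, 1e-3)
  expect_lt(abs(fit$n - 0.85) / 0.85, 1e-3)
  expect_lt(abs(fit$qd - 0.5) / 0.5, 1e-3)
  expect_equal(fit$kd, 1e6 / fit$ka, tolerance = 1e-12)
})

test_that("degenerate isotherms fail loudly", {
  zero <- tibble::tibble(injection = 1:19, heat = rep(0, 19))
  expect_error(fit_isotherm(zero, protocol), "degenerate")
  short <- tibble::tibble(injection = 1:5, heat = rnorm(5))
  expect_error(fit_isotherm(short, protocol), "at least 8")
})

test_that("Kd = 1/Ka conversion is exact in micromolar", {
  expect_equal(kd_from_ka(1e6), 1.0)
  expect_equal(signif(kd_from_ka(7.6e4), 2), 13)
  expect_equal(kd_from_ka(1.6e5), 6.25) # printed as 6.3 at the table precision
  expect_error(kd_from_ka(0), "positive")
})

test_that("thermodynamic profile closes the Gibbs identity", {
  expect_equal(thermodynamic_profile(1, 5)$dg, 0)
  p <- thermodynamic_profile(1e5, 27.7, 298.15)
  expect_equal(p$dg, -6.82, tolerance = 0.005)
  expect_equal(p$minus_tds, -34.5, tolerance = 0.02)
  expect_true(p$entropically_driven)
  # dG = dH + (-TdS) exactly, any inputs
  set.seed(5)
  for (k in 1:20) {
    pp <- thermodynamic_profile(10^runif(1, 2, 8), runif(1, -30, 40))
    expect_equal(pp$dg, pp$dh + pp$minus_tds, tolerance = 1e-12)
  }
  # an exothermic binder is not entropically driven
  expect_false(thermodynamic_profile(1e6, -10)$entropically_driven)
})

test_that("protocol validation rejects impossible geometries", {
  expect_error(itc_protocol(v0 = 10, injection_volumes = rep(2, 19)), "cell volume")
  expect_error(itc_protocol(cell_protein = 0), "")
})
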