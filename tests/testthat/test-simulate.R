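test_that("every generator at sigma = 0 equals its forward model pointwise", {
  ti <- simulate_titration(kd = 6, f0 = 100, dfmax = -40, sigma = 0)
  expect_identical(ti$fluorescence,
                   binding_curve(ti$ligand_total, 3, 6, 100, -40))

  protocol <- itc_protocol()
  iso <- simulate_itc(protocol, ka = 1e5, dh = 27.7, n = 0.85, qd = 0.5, sigma = 0)
  expect_identical(iso$heat,
                   injection_heats(protocol, 1e5, 27.7, 0.85, 0.5)$heat)

  sg <- simulate_bli(kon = 0.039, koff = 0.09, concentrations = 5, sigma = 0)
  assoc <- sg[sg$segment == "association", ]
  kd <- 0.09 / 0.039
  expect_equal(assoc$response,
               association_model(assoc$time, 5 / (5 + kd), 0.039 * 5 + 0.09),
               tolerance = 1e-12)

  dec <- simulate_dosy(d = 9.3e-7, sigma = 0)
  sol <- dec[dec$species == "solute", ]
  b <- (26752 * sol$gradient * 0.004)^2 * (0.1 - 0.004 / 3)
  expect_equal(sol$intensity, exp(-9.3e-7 * b), tolerance = 1e-12)

  st <- simulate_shift_table("AGKLV", sigma = 0)
  rc <- random_coil_shifts("AGKLV")
  expect_identical(st$delta_obs, rc$delta_rc)
})

test_that("identical seeds give identical outputs, different seeds differ", {
  a <- simulate_titration(6, 100, -40, sigma = 1, seed = 4)
  b <- simulate_titration(6, 100, -40, sigma = 1, seed = 4)
  c <- simulate_titration(6, 100, -40, sigma = 1, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, c))

  s1 <- simulate_bli(0.039, 0.09, sigma = 0.01, seed = 8)
  s2 <- simulate_bli(0.039, 0.09, sigma = 0.01, seed = 8)
  expect_identical(s1, s2)

  d1 <- simulate_dosy(sigma = 0.01, seed = 2)
  d2 <- simulate_dosy(sigma = 0.01, seed = 2)
  expect_identical(d1, d2)

  i1 <- simulate_itc(ka = 1e5, dh = 27.7, sigma = 0.3, seed = 6)
  i2 <- simulate_itc(ka = 1e5, dh = 27.7, sigma = 0.3, seed = 6)
  expect_identical(i1, i2)

  t1 <- simulate_shift_table("AGKLV", sigma = 0.02, seed = 9)
  t2 <- simulate_shift_table("AGKLV", sigma = 0.02, seed = 9)
  expect_identical(t1, t2)
})

test_that("thermogram integration returns the isotherm within 0.1%", {
  protocol <- itc_protocol()
  heats <- injection_heats(protocol, 1e5, 27.7, 0.85, 0.5)$heat
  tg <- simulate_thermogram(protocol, heats)
  back <- integrate_thermogram(tg, protocol)
  expect_lt(max(abs(back$heat - heats) / abs(heats)), 1e-3)
})

test_that("sensorgrams are continuous at every segment boundary", {
  dt <- 0.2
  sg <- simulate_bli(kon = 0.039, koff = 0.09, concentrations = c(2, 10),
                     drift_assoc = 3e-4, drift_dissoc = 1e-4, sigma = 0, dt = dt)
  boundaries <- bli_schedule()$start[-1]
  for (conc in c(2, 10)) {
    tr <- sg[sg$concentration == conc, ]
    # the jump across each boundary must shrink to the local slope scale,
    # i.e. be no larger than the largest within-segment per-sample step
    step_scale <- max(abs(diff(tr$response[!tr$time %in% boundaries])))
    for (tb in boundaries) {
      jump <- abs(tr$response[tr$time == tb] - tr$response[tr$time == tb - dt])
      expect_lt(jump, 1.5 * step_scale + 1e-12)
    }
  }
  # exact structural anchors: zero at first baseline and at association start
  tr <- sg[sg$concentration == 10, ]
  expect_equal(tr$response[tr$time == 180], 0)
  expect_true(all(tr$response[tr$time < 30] == 0))
})

test_that("the embedded kobs follows the pseudo-first-order line", {
  sg <- simulate_bli(kon = 0.039, koff = 0.09, concentrations = 5, sigma = 0)
  af <- fit_association(sg)
  expect_equal(af$kobs, 0.285, tolerance = 1e-6)
})

test_that("paired dioxane traces give the reference-based radius", {
  dec <- simulate_dosy(d = 9.3e-7, d_reference = 6.604 * 9.3e-7, sigma = 0)
  fs <- fit_decay(dec[dec$species == "solute", ])
  fr <- fit_decay(dec[dec$species == "dioxane", ])
  expect_equal(rh_from_reference(fs$d, fr$d)$rh, 14.0, tolerance = 1e-3)
})
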