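test_that("inner-filter correction is the half-absorbance multiplier", {
  expect_equal(inner_filter_correct(100, 0, 0), 100)
  expect_equal(inner_filter_correct(1, 0.1, 0.1), 10^0.1, tolerance = 1e-12)
  # monotone increasing in both absorbances, factor always >= 1
  a <- seq(0, 0.5, by = 0.1)
  expect_true(all(diff(inner_filter_correct(1, a, 0)) > 0))
  expect_true(all(inner_filter_correct(1, a, rev(a)) >= 1))
})

test_that("addition spectra and their comparison behave on constructed peaks", {
  s <- gaussian_spectrum(350)
  cmp_self <- compare_spectra(s, s)
  expect_equal(cmp_self$intensity_difference, 0)
  expect_equal(cmp_self$lambda_max_shift, 0)

  shifted <- gaussian_spectrum(355)
  expect_equal(compare_spectra(shifted, s)$lambda_max_shift, 5)

  # two well-separated fluorophore peaks both survive addition
  tyr <- gaussian_spectrum(308, width = 10)
  trp <- gaussian_spectrum(350, width = 12)
  add <- addition_spectrum(tyr, trp)
  i308 <- add$intensity[add$wavelength == 308]
  i350 <- add$intensity[add$wavelength == 350]
  i330 <- add$intensity[add$wavelength == 330]
  expect_gt(i308, i330)
  expect_gt(i350, i330)

  disjoint <- tibble::tibble(wavelength = 500:520, intensity = 1)
  expect_error(addition_spectrum(s, disjoint), "disjoint")
})

test_that("the depletion isotherm matches its closed form and the mass-balance oracle", {
  expect_equal(binding_curve(0, pt = 3, kd = 3, f0 = 7, dfmax = 1), 7)
  expect_equal(binding_curve(3, pt = 3, kd = 3, f0 = 0, dfmax = 1),
               (9 - sqrt(45)) / 6, tolerance = 1e-12)
  # stoichiometric limit: Kd -> 0 with LT >= PT saturates at F0 + dFmax
  expect_equal(binding_curve(5, pt = 3, kd = 1e-9, f0 = 2, dfmax = -1), 1,
               tolerance = 1e-6)
  # bound fraction equals the iterative equilibrium solver (Ka = 1/Kd)
  for (lt in c(0.5, 3, 12, 30)) {
    f <- binding_curve(lt, pt = 3, kd = 6, f0 = 0, dfmax = 1)
    pl <- oracle_complex_uM(pt = 3, lt = lt, ka = 1e6 / 6)
    expect_equal(f, pl / 3, tolerance = 1e-9)
  }
})

test_that("isotherm is monotone in ligand and dominated by the Kd^2 discriminant bound", {
  lt <- seq(0, 30, length.out = 40)
  up <- binding_curve(lt, 3, 5, 0, 2)
  down <- binding_curve(lt, 3, 5, 10, -2)
  expect_true(all(diff(up) >= 0))
  expect_true(all(diff(down) <= 0))
  for (kd in c(0.1, 1, 10)) {
    disc <- (3 + lt + kd)^2 - 4 * 3 * lt
    expect_true(all(disc >= kd^2 - 1e-9))
  }
})

test_that("depletion model converges to the hyperbola at first order in PT/Kd", {
  kd <- 10
  lt <- seq(0.5, 50, length.out = 25)
  hyperbola <- lt / (lt + kd)
  # deep limit: deviation is negligible
  deep <- binding_curve(lt, kd / 1e5, kd, 0, 1)
  expect_lt(max(abs(deep - hyperbola)), 1e-4)
  # convergence is first order: max deviation = 0.148 PT/Kd (at LT = Kd/2)
  for (pt in kd / c(1e3, 1e4)) {
    dev <- max(abs(binding_curve(lt, pt, kd, 0, 1) - hyperbola))
    expect_equal(dev / (pt / kd), 4 / 27, tolerance = 0.02)
  }
})

test_that("titration fitting round-trips noiseless data and flags bad regimes", {
  ti <- simulate_titration(kd = 6, f0 = 100, dfmax = -40, sigma = 0)
  fit <- fit_titration(ti, pt = 3)
  expect_lt(abs(fit$kd - 6) / 6, 1e-3)
  expect_true(fit$identifiable)

  # flat series: no signal change, explicit failure
  flat <- tibble::tibble(ligand_total = seq(0, 30, length.out = 10),
                         fluorescence = rep(50, 10))
  expect_error(fit_titration(flat, pt = 3), "flat|unidentifiable")

  # affinity beyond the accessible window raises the identifiability flag
  weak <- simulate_titration(kd = 300, f0 = 100, dfmax = -40, sigma = 0)
  fit_weak <- fit_titration(weak, pt = 3)
  expect_false(fit_weak$identifiable)
})

test_that("Kd recovery stays within 10% at 1% noise across the design grid", {
  set.seed(42)
  errs <- c()
  for (kd in c(2, 6, 15, 22)) {
    for (rep in 1:5) {
      ti <- simulate_titration(kd = kd, f0 = 100, dfmax = -40, sigma = 0.4)
      fit <- fit_titration(ti, pt = 3)
      errs <- c(errs, abs(fit$kd - kd) / kd)
    }
  }
  expect_lt(median(errs), 0.10)
})
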