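test_that("segment models satisfy their structural boundary identities", {
  set.seed(9)
  for (k in 1:25) {
    req <- runif(1, -2, 2); kobs <- runif(1, 0.01, 1); dr <- runif(1, -0.01, 0.01)
    r1 <- runif(1, -2, 2); koff <- runif(1, 0, 1)
    expect_equal(association_model(180, req, kobs, dr), 0)
    expect_equal(dissociation_model(300, r1, koff, dr), r1)
  }
  expect_error(association_model(100, 1, 0.1), "t >= t0")
  expect_error(dissociation_model(100, 1, 0.1), "t >= t0")
})

test_that("segment models match their closed forms", {
  kobs <- 0.129
  expect_equal(association_model(180 + 1 / kobs, 1, kobs), 1 - exp(-1),
               tolerance = 1e-12)
  # zero drift plateau
  expect_equal(association_model(1e6, 0.7, 0.1), 0.7, tolerance = 1e-9)
  koff <- 0.09
  expect_equal(dissociation_model(300 + log(2) / koff, 2, koff), 1,
               tolerance = 1e-12)
  expect_equal(dissociation_model(420, 2, 0), 2)
})

test_that("segment fits invert the noiseless simulator", {
  sg <- simulate_bli(kon = 0.039, koff = 0.09, rmax = 1,
                     concentrations = 5, sigma = 0)
  af <- fit_association(sg)
  kd <- 0.09 / 0.039
  expect_lt(abs(af$kobs - (0.039 * 5 + 0.09)) / 0.285, 1e-6)
  expect_lt(abs(af$req - 5 / (5 + kd)) / (5 / (5 + kd)), 1e-6)
  df <- fit_dissociation(sg)
  expect_lt(abs(df$koff - 0.09) / 0.09, 1e-6)
})

test_that("drift terms are recovered alongside the rates", {
  sg <- simulate_bli(kon = 0.039, koff = 0.09, concentrations = 5,
                     drift_assoc = 5e-4, drift_dissoc = 2e-4, sigma = 0)
  af <- fit_association(sg)
  df <- fit_dissociation(sg)
  expect_equal(af$drift, 5e-4, tolerance = 1e-4)
  expect_equal(df$drift, 2e-4, tolerance = 1e-4)
  expect_lt(abs(af$kobs - 0.285) / 0.285, 1e-5)
  expect_lt(abs(df$koff - 0.09) / 0.09, 1e-4)
})

test_that("pure-noise segments fail instead of returning numbers", {
  set.seed(31)
  t <- seq(0, 420, by = 0.2)
  noise <- tibble::tibble(time = t, response = rnorm(length(t), 0, 0.01))
  expect_error(
    tryCatch(fit_association(noise), warning = function(w) stop(w)),
    "unreliable|converge|singular"
  )
})

test_that("pseudo-first-order regression is exact on exact inputs", {
  pfo <- pseudo_first_order(c(0.129, 0.168, 0.285, 0.48), c(1, 2, 5, 10))
  expect_equal(pfo$kon, 0.039, tolerance = 1e-12)
  expect_equal(pfo$koff, 0.09, tolerance = 1e-12)
  expect_error(pseudo_first_order(c(0.1, 0.2), c(1, 1)), "3 distinct")
  expect_warning(
    neg <- pseudo_first_order(c(0.01, 0.05, 0.09), c(2, 6, 10)),
    "negative"
  )
  expect_lt(neg$koff, 0)
  expect_equal(neg$koff_floored, 0)
})

test_that("Kd derives from the rates with quadrature error propagation", {
  expect_equal(signif(kd_from_rates(0.039, 0.09)$kd, 2), 2.3)
  expect_equal(signif(kd_from_rates(0.05, 0.06)$kd, 2), 1.2)
  expect_equal(kd_from_rates(0.06, 0)$kd, 0)
  r <- kd_from_rates(0.039, 0.09, 0.003, 0.01)
  expect_equal(r$sigma_kd,
               (0.09 / 0.039) * sqrt((0.003 / 0.039)^2 + (0.01 / 0.09)^2),
               tolerance = 1e-12)
  expect_error(kd_from_rates(0, 0.1), "positive")
})

test_that("full kinetic analysis recovers the generator and stores Kd = koff/kon", {
  sg <- simulate_bli(kon = 0.039, koff = 0.09, sigma = 0)
  fit <- fit_kinetics(sg)
  expect_lt(abs(fit$kon - 0.039) / 0.039, 1e-6)
  expect_lt(abs(fit$koff - 0.09) / 0.09, 1e-6)
  expect_identical(fit$kd, fit$koff / fit$kon)
  # kobs is affine in concentration under the two-state generator
  expect_equal(fit$traces$kobs, 0.039 * fit$traces$concentration + 0.09,
               tolerance = 1e-6)
})
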