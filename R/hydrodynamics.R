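#' Fit a pulsed-field-gradient diffusion decay
#'
#' Fits the Stejskal-Tanner mono-exponential decay
#' \deqn{I(g) = I_0 \exp(-D (\gamma g \delta)^2 (\Delta - \delta/3))}
#' to a gradient-strength vs. intensity table by nonlinear least squares,
#' returning the translational self-diffusion coefficient D and its fitting
#' uncertainty from the covariance matrix.
#'
#' @param data A data frame with gradient strengths and intensities.
#' @param gradient,intensity Column names (tidy-eval) holding gradient
#'   strength (G cm-1) and signal intensity (arbitrary units).
#' @param gamma Gyromagnetic factor (rad s-1 G-1); default is 1H.
#' @param delta Gradient pulse length delta (s).
#' @param big_delta Diffusion delay Delta (s).
#' @return An object of class `dosy_fit`: a list with `d` (cm2 s-1),
#'   `sigma_d`, `i0`, `n`, and the fitted model.
#' @export
#' @examples
#' dec <- simulate_dosy(d = 9.3e-7, sigma = 0)
#' fit_decay(dplyr::filter(dec, species == "solute"))
fit_decay <- function(data, gradient = gradient, intensity = intensity,
                      gamma = 26752, delta = 0.004, big_delta = 0.1) {
  g <- dplyr::pull(data, {{ gradient }})
  i <- dplyr::pull(data, {{ intensity }})
  if (length(g) < 3) abort("need at least 3 gradient points to fit a decay")
  # noise on a fully decayed tail may dip just below zero; only grossly
  # negative intensities indicate corrupt input
  if (any(i < -0.05 * max(i))) abort("intensities must be non-negative")
  b <- (gamma * g * delta)^2 * (big_delta - delta / 3)
  # decaying trend check: intensity must fall with b
  if (diff(range(i)) / max(i) < 1e-9 || stats::cor(b, i) >= 0) {
    abort("intensities do not decay with gradient strength; cannot fit D")
  }
  # log-linear start, then full nonlinear refinement
  pos <- i > 0
  start_fit <- lm(log(i[pos]) ~ b[pos])
  d0 <- unname(max(-coef(start_fit)[2], 1e-12))
  i00 <- unname(exp(coef(start_fit)[1]))
  df <- tibble(b = b, i = i)
  fit <- minpack.lm::nlsLM(
    i ~ i0 * exp(-d * b), data = df,
    start = list(i0 = i00, d = d0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  if (est[["d"]] <= 0) abort("fitted diffusion coefficient is non-positive")
  structure(
    list(d = unname(est[["d"]]), sigma_d = unname(se[["d"]]),
         i0 = unname(est[["i0"]]), n = length(g), fit = fit,
         gamma = gamma, delta = delta, big_delta = big_delta,
         data = tibble(gradient = g, intensity = i, b = b)),
    class = "dosy_fit"
  )
}

#' @export
print.dosy_fit <- function(x, ...) {
  cat(sprintf("PFG diffusion fit: D = %.4g +/- %.2g cm2 s-1 (n = %d)\n",
              x$d, x$sigma_d, x$n))
  invisible(x)
}

#' Hydrodynamic radius from an internal diffusion reference
#'
#' Stokes-Einstein ratio method: with dioxane (Rh = 2.12 A) co-dissolved as
#' an internal reference, temperature and viscosity cancel and
#' \eqn{R_h = R_{h,ref} \cdot D_{ref} / D_{solute}}. Uncertainty is
#' first-order quadrature of the relative errors of the two D values.
#'
#' @param d_solute,d_reference Diffusion coefficients (same units), > 0.
#' @param sigma_solute,sigma_reference Their uncertainties.
#' @param rh_reference Reference hydrodynamic radius in Angstrom (dioxane:
#'   2.12).
#' @return A tibble with `rh` (Angstrom), `sigma` and `method`.
#' @export
rh_from_reference <- function(d_solute, d_reference,
                              sigma_solute = 0, sigma_reference = 0,
                              rh_reference = 2.12) {
  if (any(d_solute <= 0) || any(d_reference <= 0)) {
    abort("diffusion coefficients must be positive")
  }
  rh <- rh_reference * d_reference / d_solute
  sigma <- rh * sqrt((sigma_solute / d_solute)^2 + (sigma_reference / d_reference)^2)
  tibble(rh = rh, sigma = sigma, method = "dioxane-reference")
}

#' Random-coil hydrodynamic radius from molecular weight
#'
#' Empirical scaling law for disordered polypeptides,
#' \eqn{R_h = a \cdot MW^{b}} with Rh in nm and MW in Da
#' (a = 0.027 +/- 0.01 nm Da^-b, b = 0.50 +/- 0.01 by default), converted to
#' Angstrom. Uncertainty by first-order propagation of sigma_a and sigma_b.
#'
#' @param mw Molecular weight in Da, > 0.
#' @param coefficient,exponent Scaling-law parameters a and b.
#' @param sigma_coefficient,sigma_exponent Their uncertainties.
#' @return A tibble with `rh` (Angstrom), `sigma` and `method`.
#' @export
#' @examples
#' rh_random_coil(3697.16) # ~16 Angstrom
rh_random_coil <- function(mw, coefficient = 0.027, exponent = 0.50,
                           sigma_coefficient = 0.01, sigma_exponent = 0.01) {
  if (any(mw <= 0)) abort("molecular weight must be positive")
  stopifnot(coefficient > 0, exponent > 0, exponent < 1)
  rh_nm <- coefficient * mw^exponent
  # d(rh)/da = MW^b ; d(rh)/db = a MW^b ln(MW)
  lnmw <- ifelse(mw > 0, log(mw), 0)
  sigma_nm <- sqrt((mw^exponent * sigma_coefficient)^2 +
                     (rh_nm * lnmw * sigma_exponent)^2)
  tibble(rh = 10 * rh_nm, sigma = 10 * sigma_nm, method = "scaling-law")
}

#' Consistency of measured vs. random-coil predicted radius
#'
#' A peptide is judged consistent with a monomeric, disordered chain when
#' the measured and predicted hydrodynamic radii agree within the sum of
#' their uncertainties.
#'
#' @param rh_measured,sigma_measured Measured radius and uncertainty (A).
#' @param rh_predicted,sigma_predicted Scaling-law radius and uncertainty (A).
#' @return A tibble with `verdict` ("consistent"/"inconsistent"), the
#'   absolute `difference` and the allowed `margin`.
#' @export
assess_monomeric_disordered <- function(rh_measured, sigma_measured,
                                        rh_predicted, sigma_predicted) {
  stopifnot(all(sigma_measured >= 0), all(sigma_predicted >= 0))
  difference <- abs(rh_measured - rh_predicted)
  margin <- sigma_measured + sigma_predicted
  tibble(
    verdict = ifelse(difference <= margin, "consistent", "inconsistent"),
    difference = difference, margin = margin
  )
}
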