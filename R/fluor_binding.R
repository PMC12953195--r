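#' Inner-filter correction of fluorescence intensities
#'
#' Standard half-absorbance correction
#' \eqn{F_{corr} = F_{obs} \cdot 10^{(A_{ex} + A_{em})/2}}, compensating the
#' attenuation of excitation and emission light by sample absorbance. The
#' multiplier is always >= 1 for non-negative absorbances.
#'
#' @param f_obs Observed (blank-subtracted) fluorescence.
#' @param a_excitation,a_emission Absorbance at the excitation and emission
#'   wavelengths (AU), >= 0.
#' @return Corrected fluorescence, same units as `f_obs`.
#' @export
inner_filter_correct <- function(f_obs, a_excitation = 0, a_emission = 0) {
  stopifnot(all(a_excitation >= 0), all(a_emission >= 0))
  f_obs * 10^((a_excitation + a_emission) / 2)
}

.resample_common_grid <- function(s1, s2) {
  lo <- max(min(s1$wavelength), min(s2$wavelength))
  hi <- min(max(s1$wavelength), max(s2$wavelength))
  if (lo >= hi) abort("spectra have disjoint wavelength ranges")
  grid <- sort(unique(c(
    s1$wavelength[s1$wavelength >= lo & s1$wavelength <= hi],
    s2$wavelength[s2$wavelength >= lo & s2$wavelength <= hi]
  )))
  list(
    grid = grid,
    i1 = approx(s1$wavelength, s1$intensity, grid)$y,
    i2 = approx(s2$wavelength, s2$intensity, grid)$y
  )
}

#' Pointwise sum of two emission spectra
#'
#' Adds the spectra of two isolated species (resampling to the common
#' wavelength grid by linear interpolation) to form the "addition spectrum"
#' against which the spectrum of the complex is compared: deviations signal
#' binding-induced changes in the fluorophore environments.
#'
#' @param s1,s2 Data frames with columns `wavelength` (nm, strictly
#'   increasing) and `intensity`.
#' @return A tibble with `wavelength` and `intensity` on the common grid.
#' @export
addition_spectrum <- function(s1, s2) {
  stopifnot(all(diff(s1$wavelength) > 0), all(diff(s2$wavelength) > 0))
  rs <- .resample_common_grid(s1, s2)
  tibble(wavelength = rs$grid, intensity = rs$i1 + rs$i2)
}

#' Compare a complex spectrum against an addition spectrum
#'
#' Reports the intensity difference (complex minus addition) at the addition
#' spectrum's emission maximum and the shift of the wavelength of maximum
#' emission.
#'
#' @param complex,addition Spectra (data frames with `wavelength`,
#'   `intensity`).
#' @return A tibble with `intensity_difference`, `lambda_max_shift` (nm),
#'   `lambda_max_complex` and `lambda_max_addition`.
#' @export
compare_spectra <- function(complex, addition) {
  rs <- .resample_common_grid(complex, addition)
  lam_add <- rs$grid[which.max(rs$i2)]
  lam_cpx <- rs$grid[which.max(rs$i1)]
  at_max <- which.max(rs$i2)
  tibble(
    intensity_difference = rs$i1[at_max] - rs$i2[at_max],
    lambda_max_shift = lam_cpx - lam_add,
    lambda_max_complex = lam_cpx,
    lambda_max_addition = lam_add
  )
}

#' Ligand-depletion binding isotherm (forward model)
#'
#' Fluorescence signal for a 1:1 complex when the titrated ligand is
#' depleted appreciably by binding, so the bound fraction follows the
#' quadratic mass-balance root rather than the hyperbola:
#' \deqn{F = F_0 + \frac{\Delta F_{max}}{2 P_T}\left[(P_T + L_T + K_d) -
#'   \sqrt{(P_T + L_T + K_d)^2 - 4 P_T L_T}\right]}
#' with \eqn{P_T} the fixed receptor (importin) concentration and \eqn{L_T}
#' the total peptide concentration. The discriminant is clipped at zero
#' against floating-point rounding (algebraically it is >= Kd^2).
#'
#' @param lt Total ligand (peptide) concentrations, uM.
#' @param pt Fixed total receptor concentration, uM (> 0).
#' @param kd Dissociation constant, uM (> 0).
#' @param f0 Signal at zero ligand.
#' @param dfmax Maximal signal change at saturation (any sign).
#' @return Numeric vector of signals.
#' @export
#' @examples
#' binding_curve(lt = 3, pt = 3, kd = 3, f0 = 0, dfmax = 1) # 0.3820
binding_curve <- function(lt, pt, kd, f0, dfmax) {
  if (pt <= 0) abort("receptor concentration pt must be positive")
  if (kd <= 0) abort("kd must be positive")
  s <- pt + lt + kd
  disc <- pmax(s^2 - 4 * pt * lt, 0)
  f0 + dfmax / (2 * pt) * (s - sqrt(disc))
}

#' Fit a fluorescence titration to the ligand-depletion isotherm
#'
#' Nonlinear least squares over (Kd, F0, dFmax), unweighted by default.
#' Uncertainties come from the fit covariance. An identifiability flag is
#' raised when the fitted Kd falls outside the window the design can
#' constrain: above ~10x the largest ligand concentration (curve too
#' shallow) or below ~PT/10 (titration stoichiometric, curvature carries no
#' Kd information). Degenerate series (no signal change) fail explicitly.
#'
#' @param data A data frame with the titration.
#' @param ligand,signal Columns (tidy-eval) holding total peptide
#'   concentration (uM) and blank-subtracted signal.
#' @param pt Fixed receptor concentration, uM.
#' @param weights Optional per-point weights for weighted least squares.
#' @param start Optional named list of starting values (`kd`, `f0`, `dfmax`).
#' @return Object of class `fluor_fit`: estimates, standard errors,
#'   residual norm, `identifiable` flag and window, the data, the fit.
#' @export
#' @examples
#' ti <- simulate_titration(kd = 6, f0 = 100, dfmax = -40, sigma = 0)
#' fit_titration(ti, pt = 3)
fit_titration <- function(data, ligand = ligand_total, signal = fluorescence,
                          pt = 3, weights = NULL, start = NULL) {
  lt <- dplyr::pull(data, {{ ligand }})
  f <- dplyr::pull(data, {{ signal }})
  if (length(lt) < 5) abort("need at least 5 titration points")
  if (any(lt < 0)) abort("ligand concentrations must be non-negative")
  if (sum(lt > 0) < 2 || max(lt[lt > 0]) / min(lt[lt > 0]) < 3) {
    abort("titration must span at least a 3-fold ligand concentration range")
  }
  if (diff(range(f)) < .Machine$double.eps^0.5 * max(abs(f), 1)) {
    abort("flat titration series: signal change is zero, Kd unidentifiable")
  }
  start <- start %||% list(
    kd = max(median(lt), pt / 2),
    f0 = f[which.min(lt)],
    dfmax = f[which.max(lt)] - f[which.min(lt)]
  )
  df <- tibble(lt = lt, f = f)
  args <- list(
    f ~ binding_curve(lt, pt, kd, f0, dfmax),
    data = df, start = start,
    lower = c(kd = 1e-6, f0 = -Inf, dfmax = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e) abort(paste("titration fit did not converge:", conditionMessage(e)))
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  window <- c(lower = pt / 10, upper = 10 * max(lt))
  # boundary-inclusive flagging with a float-safe tolerance: a Kd at ~10x
  # the largest LT (or ~PT/10) is already outside the constrained regime
  identifiable <- est[["kd"]] < window[["upper"]] * (1 - 1e-6) &&
    est[["kd"]] > window[["lower"]] * (1 + 1e-6)
  structure(
    list(
      kd = unname(est[["kd"]]), sigma_kd = unname(se[["kd"]]),
      f0 = unname(est[["f0"]]), sigma_f0 = unname(se[["f0"]]),
      dfmax = unname(est[["dfmax"]]), sigma_dfmax = unname(se[["dfmax"]]),
      pt = pt, residual_norm = sqrt(sum(stats::resid(fit)^2)),
      identifiable = identifiable, identifiability_window = window,
      n = length(lt), data = df, fit = fit
    ),
    class = "fluor_fit"
  )
}

#' @export
print.fluor_fit <- function(x, ...) {
  cat(sprintf("Ligand-depletion titration fit (PT = %g uM, n = %d)\n", x$pt, x$n))
  cat(sprintf("  Kd    = %.4g +/- %.2g uM%s\n", x$kd, x$sigma_kd,
              if (x$identifiable) "" else "  [outside identifiable window]"))
  cat(sprintf("  F0    = %.4g +/- %.2g\n", x$f0, x$sigma_f0))
  cat(sprintf("  dFmax = %.4g +/- %.2g\n", x$dfmax, x$sigma_dfmax))
  invisible(x)
}
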