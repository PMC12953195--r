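#' Injection protocol for a single-site ITC titration
#'
#' Geometry and concentrations of an overflow-cell titration. Defaults match
#' a 19 x 2 uL injection sequence into a 200.3 uL cell with 10 uM protein
#' titrated by 100 uM peptide at 25 C.
#'
#' @param v0 Cell volume, uL.
#' @param injection_volumes Vector of injection volumes v_k, uL.
#' @param syringe_ligand Ligand (peptide) concentration in the syringe, uM.
#' @param cell_protein Initial protein concentration in the cell, uM.
#' @param temperature Temperature, K.
#' @return A list of class `itc_protocol`.
#' @export
itc_protocol <- function(v0 = 200.3, injection_volumes = rep(2, 19),
                         syringe_ligand = 100, cell_protein = 10,
                         temperature = 298.15) {
  stopifnot(v0 > 0, all(injection_volumes > 0),
            syringe_ligand > 0, cell_protein > 0, temperature > 0)
  if (sum(injection_volumes) >= v0) {
    abort("total injected volume must be smaller than the cell volume")
  }
  structure(
    list(v0 = v0, injection_volumes = injection_volumes,
         syringe_ligand = syringe_ligand, cell_protein = cell_protein,
         temperature = temperature),
    class = "itc_protocol"
  )
}

#' Ligand and protein concentrations in the cell after each injection
#'
#' Overflow-mode dilution: each injection of volume v_k displaces an equal
#' volume of cell content, so after injection j
#' \deqn{L_{T,j} = [L]_{syr}\left(1 - \prod_{k \le j}(1 - v_k/V_0)\right),
#'   \qquad P_{T,j} = [P]_{cell}\prod_{k \le j}(1 - v_k/V_0).}
#'
#' @param protocol An [itc_protocol()].
#' @param j Injection indices to report (default: all).
#' @return A tibble with `injection`, `lt` (uM), `pt` (uM), `molar_ratio`.
#' @export
#' @examples
#' cell_concentrations(itc_protocol())
cell_concentrations <- function(protocol, j = NULL) {
  nv <- length(protocol$injection_volumes)
  j <- j %||% seq_len(nv)
  if (any(j < 1 | j > nv)) abort(sprintf("injection index out of range 1..%d", nv))
  dil <- cumprod(1 - protocol$injection_volumes / protocol$v0)
  lt <- protocol$syringe_ligand * (1 - dil)
  pt <- protocol$cell_protein * dil
  tibble(injection = as.integer(j), lt = lt[j], pt = pt[j],
         molar_ratio = lt[j] / pt[j])
}

#' Equilibrium complex concentration for single-site binding
#'
#' Closed-form root of the 1:1 mass-balance with an apparent stoichiometry
#' factor n scaling the binding-competent protein:
#' \deqn{[PL] = \frac{(1 + K_a n P_T + K_a L_T) -
#'   \sqrt{(1 + K_a n P_T + K_a L_T)^2 - 4 K_a^2 n P_T L_T}}{2 K_a}.}
#' Concentration arguments are uM; Ka is M-1 (conversion handled
#' internally). The result is bounded by 0 <= [PL] <= min(n PT, LT).
#'
#' @param pt,lt Total protein and ligand concentrations, uM.
#' @param ka Association constant, M-1 (> 0).
#' @param n Apparent stoichiometry (> 0).
#' @return Complex concentration [PL], uM.
#' @export
#' @examples
#' complex_concentration(pt = 10, lt = 5, ka = 1e5, n = 1) # 2.192 uM
complex_concentration <- function(pt, lt, ka, n = 1) {
  if (any(ka <= 0)) abort("ka must be positive")
  if (any(n <= 0)) abort("stoichiometry n must be positive")
  if (any(pt < 0) || any(lt < 0)) abort("concentrations must be non-negative")
  p <- n * pt * 1e-6   # M
  l <- lt * 1e-6       # M
  s <- 1 + ka * p + ka * l
  disc <- pmax(s^2 - 4 * ka^2 * p * l, 0)
  pl <- (s - sqrt(disc)) / (2 * ka)
  pmin(pmax(pl, 0), pmin(p, l)) * 1e6  # back to uM, clipped to mass balance
}

#' Theoretical ligand-normalized injection heats
#'
#' Forward model of the single-site ITC isotherm: the heat of injection j,
#' normalized per mole of injected ligand, is
#' \deqn{Q_j = \frac{V_0 \Delta H}{v_j [L]_{syr}}
#'   \left([PL]_j - [PL]_{j-1}(1 - v_j/V_0)\right) + Q_d}
#' with \eqn{[PL]_0 = 0}. Volumes in uL and concentrations in uM cancel in
#' the prefactor, so Q_j carries the units of dH (kcal per mol of
#' injectant) plus the background heat Qd.
#'
#' @param protocol An [itc_protocol()].
#' @param ka Association constant, M-1.
#' @param dh Binding enthalpy, kcal mol-1.
#' @param n Apparent stoichiometry.
#' @param qd Background ("dilution") heat, kcal mol-1 of injectant.
#' @return A tibble with `injection`, `molar_ratio`, `heat` (kcal mol-1).
#' @export
injection_heats <- function(protocol, ka, dh, n = 1, qd = 0) {
  cc <- cell_concentrations(protocol)
  pl <- complex_concentration(cc$pt, cc$lt, ka, n)
  v <- protocol$injection_volumes
  pl_prev <- c(0, head(pl, -1))
  q <- protocol$v0 * dh * (pl - pl_prev * (1 - v / protocol$v0)) /
    (v * protocol$syringe_ligand) + qd
  tibble(injection = cc$injection, molar_ratio = cc$molar_ratio, heat = q)
}

#' Fit an ITC isotherm to the single-site injection model
#'
#' Nonlinear least squares over (Ka, dH, n, Qd) with Ka parameterized on the
#' log scale to enforce positivity. Starting values are taken from the data:
#' Qd from the post-saturation tail, dH from the first-injection excess over
#' the tail, n from the molar ratio at the isotherm midpoint. Uncertainties
#' come from the covariance matrix; Kd = 1/Ka is reported in uM. Degenerate
#' isotherms (no heat signal) and non-convergent fits fail explicitly.
#'
#' @param isotherm A data frame with per-injection heats.
#' @param protocol The [itc_protocol()] used.
#' @param injection,heat Columns (tidy-eval) with the injection index and
#'   ligand-normalized heat (kcal per mol of injectant).
#' @param start Optional named list overriding starting values
#'   (`ka`, `dh`, `n`, `qd`).
#' @return Object of class `itc_fit` with estimates, standard errors, the
#'   derived Kd (uM), the thermodynamic profile at the protocol temperature,
#'   and fit diagnostics.
#' @export
#' @examples
#' iso <- simulate_itc(itc_protocol(), ka = 1e5, dh = 27.7, n = 0.85, qd = 0.5)
#' fit_isotherm(iso, itc_protocol())
fit_isotherm <- function(isotherm, protocol, injection = injection, heat = heat,
                         start = NULL) {
  jj <- dplyr::pull(isotherm, {{ injection }})
  q <- dplyr::pull(isotherm, {{ heat }})
  if (length(q) < 8) abort("need at least 8 injections to fit the isotherm")
  if (diff(range(q)) < 1e-12 * max(abs(q), 1) || all(q == 0)) {
    abort("isotherm carries no heat signal; fit is degenerate")
  }
  cc <- cell_concentrations(protocol, jj)
  qd0 <- mean(tail(q, 3))
  dh0 <- q[1] - qd0
  if (abs(dh0) < 1e-9) dh0 <- sign(q[1] - qd0 + 1e-12) * max(abs(q - qd0))
  half <- qd0 + dh0 / 2
  n0 <- tryCatch({
    cross <- which(diff(sign(q - half)) != 0)[1]
    if (is.na(cross)) 1 else mean(cc$molar_ratio[cross + 0:1])
  }, error = function(e) 1)
  if (!is.finite(n0) || n0 <= 0.05) n0 <- 1
  start <- start %||% list(ka = 1e5, dh = dh0, n = n0, qd = qd0)
  df <- tibble(j = jj, q = q)
  model_fun <- function(log10_ka, dh, n, qd) {
    injection_heats(protocol, 10^log10_ka, dh, n, qd)$heat[jj]
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      q ~ model_fun(log10_ka, dh, n, qd), data = df,
      start = list(log10_ka = log10(start$ka), dh = start$dh,
                   n = start$n, qd = start$qd),
      lower = c(log10_ka = 0, dh = -Inf, n = 1e-3, qd = -Inf),
      upper = c(log10_ka = 12, dh = Inf, n = 10, qd = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) abort(paste("ITC fit did not converge:", conditionMessage(e)))
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
  ka_hat <- 10^est[["log10_ka"]]
  sigma_ka <- ka_hat * log(10) * se[["log10_ka"]]
  kd_hat <- kd_from_ka(ka_hat)
  profile <- thermodynamic_profile(ka_hat, est[["dh"]], protocol$temperature)
  # c-value diagnostic: c = n Ka [P]; fits are unreliable far outside 1..1000
  c_value <- est[["n"]] * ka_hat * protocol$cell_protein * 1e-6
  structure(
    list(
      ka = ka_hat, sigma_ka = unname(sigma_ka),
      kd = kd_hat, sigma_kd = kd_hat * unname(sigma_ka) / ka_hat,
      dh = unname(est[["dh"]]), sigma_dh = unname(se[["dh"]]),
      n = unname(est[["n"]]), sigma_n = unname(se[["n"]]),
      qd = unname(est[["qd"]]), sigma_qd = unname(se[["qd"]]),
      c_value = unname(c_value), profile = profile,
      residual_norm = sqrt(sum(stats::resid(fit)^2)),
      temperature = protocol$temperature,
      n_injections = length(q), data = df, fit = fit
    ),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("Single-site ITC fit (%d injections, T = %.2f K)\n",
              x$n_injections, x$temperature))
  cat(sprintf("  Ka = %.3g +/- %.2g M-1   (Kd = %.3g uM)\n", x$ka, x$sigma_ka, x$kd))
  cat(sprintf("  dH = %.3g +/- %.2g kcal/mol   n = %.3g +/- %.2g   Qd = %.3g\n",
              x$dh, x$sigma_dh, x$n, x$sigma_n, x$qd))
  cat(sprintf("  dG = %.3g, -TdS = %.3g kcal/mol (%s)\n",
              x$profile$dg, x$profile$minus_tds,
              if (x$profile$entropically_driven) "entropically driven" else
                "not entropically driven"))
  invisible(x)
}

#' Dissociation constant from the association constant
#'
#' Kd = 1/Ka converted to micromolar (10^6 / Ka with Ka in M-1).
#'
#' @param ka Association constant, M-1 (> 0).
#' @return Kd in uM.
#' @export
#' @examples
#' kd_from_ka(1.6e5) # 6.25 uM
kd_from_ka <- function(ka) {
  if (any(ka <= 0)) abort("ka must be positive")
  1e6 / ka
}

#' Thermodynamic binding profile from Ka and dH
#'
#' \eqn{\Delta G = -RT \ln K_a} (R = 1.987e-3 kcal mol-1 K-1) and
#' \eqn{-T\Delta S = \Delta G - \Delta H}, so that
#' \eqn{\Delta G = \Delta H + (-T\Delta S)} holds exactly. Binding is judged
#' entropically driven when the enthalpic term opposes binding (dH > 0) and
#' the entropic term favors it (-TdS < 0).
#'
#' @param ka Association constant, M-1.
#' @param dh Binding enthalpy, kcal mol-1.
#' @param temperature Temperature, K.
#' @return A tibble with `dg`, `dh`, `minus_tds` (kcal mol-1),
#'   `temperature` and `entropically_driven`.
#' @export
#' @examples
#' thermodynamic_profile(1e5, 27.7) # dG = -6.82, -TdS = -34.5
thermodynamic_profile <- function(ka, dh, temperature = 298.15) {
  if (any(ka <= 0)) abort("ka must be positive")
  stopifnot(all(temperature > 0))
  dg <- -.R_KCAL * temperature * log(ka)
  minus_tds <- dg - dh
  tibble(dg = dg, dh = dh, minus_tds = minus_tds, temperature = temperature,
         entropically_driven = minus_tds < 0 & dh > 0)
}
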