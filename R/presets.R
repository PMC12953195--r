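#' Annotated sequences and hydrodynamic reference values of the PADI NLS peptides
#'
#' The four soluble NLS peptides studied (one each from PADI1 and PADI2,
#' two from PADI3) as annotated-sequence strings with intact-protein
#' numbering, together with their published molecular weights, measured
#' diffusion coefficients and hydrodynamic radii. These printed values are
#' inputs for simulations and consistency checks, never fit targets.
#'
#' @return A tibble with `entry` (annotated string), `name`, `mw_printed`
#'   (Da), `d_printed` (cm2 s-1), `sigma_d`, `rh_reference_printed` (A),
#'   `sigma_rh_reference`, `rh_scaling_printed` (A), `sigma_rh_scaling`.
#' @export
padi_peptide_presets <- function() {
  tibble(
    entry = c(
      "K^520^HQAKRSINEMLADRHLQRDNLHAQKSIDW^549^ (PADI1-NLS1)",
      "K^499^LFREKQKDGHGEAIMFKGLGGMSSKRIT^527^Y (PADI2-NLS2)",
      "H^361^KTLPVVFDSPRNGELQDFPYKRIL^385^ (PADI3-NLS1)",
      "R^552^EVLKRELGLAESDIIDIPQLFKTERKKAT^581^ (PADI3-NLS2)"
    ),
    name = c("PADI1-NLS1", "PADI2-NLS2", "PADI3-NLS1", "PADI3-NLS2"),
    mw_printed = c(3697.16, 3455.00, 3011.42, 3539.08),
    d_printed = c(9.3e-7, 9.08e-7, 9.10e-7, 9.4e-7),
    sigma_d = c(0.1e-7, 0.09e-7, 0.09e-7, 0.3e-7),
    rh_reference_printed = c(14, 14, 14, 14),
    sigma_rh_reference = c(3, 2, 2, 3),
    rh_scaling_printed = c(16, 15, 14, 16),
    sigma_rh_scaling = c(2, 2, 2, 2)
  )
}

#' Published ITC parameters of the NLS peptide / importin pairs
#'
#' Single-site ITC parameters (Ka, printed Kd, dH, n) for each
#' (peptide, importin species) pair, used as realistic simulation presets
#' and for the Kd = 1/Ka arithmetic. `kd_consistent` flags cells whose
#' printed Kd agrees with 1/Ka to within 5% (one PADI2-NLS2 cell prints a
#' Kd that is mutually inconsistent with its Ka, presumably a typographical
#' exponent error, and is excluded from arithmetic checks).
#'
#' @return A tibble with `peptide`, `importin`, `ka` (M-1), `kd_printed`
#'   (uM), `dh` (kcal mol-1), `n`, `kd_consistent`.
#' @export
padi_itc_presets <- function() {
  out <- tibble(
    peptide = rep(c("PADI1-NLS1", "PADI2-NLS2", "PADI3-NLS1", "PADI3-NLS2"), each = 2),
    importin = rep(c("Impa3", "dImpa3"), times = 4),
    ka = c(1e5, 7.0e5, 7.6e4, 8.7e4, 1.6e5, 8.0e5, 1.2e5, 6.0e5),
    kd_printed = c(9.8, 1.4, 13, 1.2, 6.3, 1.3, 8.1, 1.7),
    dh = c(27.7, 15.9, 34.4, 19.2, 9.6, 16.7, 2.8, 11.3),
    n = c(0.85, 0.87, 0.96, 0.81, 0.84, 0.82, 0.85, 0.95)
  )
  out$kd_consistent <- abs(kd_from_ka(out$ka) - out$kd_printed) / out$kd_printed <= 0.05
  out
}

#' Published BLI kinetic rates of the NLS peptide / importin pairs
#'
#' Association and dissociation rates with their printed uncertainties and
#' the derived Kd = koff/kon, used as simulation presets and for the rate
#' arithmetic. One peptide gave no reliable sensorgrams (rows with NA).
#' `kd_consistent` flags rows whose printed Kd matches koff/kon at the
#' printed precision (one pair's printed Kd differs from the ratio of its
#' printed rates, presumably computed from unrounded values, and is
#' excluded from exact checks).
#'
#' @return A tibble with `peptide`, `importin`, `kon` (uM-1 s-1),
#'   `sigma_kon`, `koff` (s-1), `sigma_koff`, `kd_printed` (uM),
#'   `sigma_kd`, `kd_consistent`.
#' @export
padi_bli_presets <- function() {
  tibble(
    peptide = rep(c("PADI1-NLS1", "PADI2-NLS2", "PADI3-NLS1", "PADI3-NLS2"), each = 2),
    importin = rep(c("Impa3", "dImpa3"), times = 4),
    kon = c(0.039, 0.03, 0.038, 0.05, NA, NA, 0.008, 0.006),
    sigma_kon = c(0.003, 0.01, 0.007, 0.01, NA, NA, 0.002, 0.002),
    koff = c(0.09, 0.06, 0.09, 0.06, NA, NA, 0.014, 0.16),
    sigma_koff = c(0.01, 0.03, 0.02, 0.05, NA, NA, 0.010, 0.01),
    kd_printed = c(2.3, 2.0, 2.4, 1.2, NA, NA, 2, 24),
    sigma_kd = c(0.5, 0.9, 0.6, 0.7, NA, NA, 1, 12),
    kd_consistent = c(TRUE, TRUE, TRUE, TRUE, NA, NA, FALSE, FALSE)
  )
}

#' Published fluorescence-titration dissociation constants
#'
#' Kd values from ligand-depletion isotherm fits of fluorescence
#' titrations; NA marks pairs where a signal change was observed but no
#' trustworthy Kd could be fitted (affinity outside the accessible window
#' at the concentrations used).
#'
#' @return A tibble with `peptide`, `importin`, `kd` (uM), `sigma_kd`.
#' @export
padi_fluor_presets <- function() {
  tibble(
    peptide = rep(c("PADI1-NLS1", "PADI2-NLS2", "PADI3-NLS1", "PADI3-NLS2"), each = 2),
    importin = rep(c("Impa3", "dImpa3"), times = 4),
    kd = c(15, NA, 22, 8, NA, NA, 6, 16),
    sigma_kd = c(12, NA, 9, 2, NA, NA, 3, 12)
  )
}
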