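## Seeded Gaussian noise; seed = NULL leaves the ambient RNG stream alone.
.add_noise <- function(x, sigma, seed = NULL) {
  if (sigma < 0) abort("noise sigma must be non-negative")
  if (sigma == 0) return(x)
  noise <- if (is.null(seed)) {
    rnorm(length(x), 0, sigma)
  } else {
    withr::with_seed(seed, rnorm(length(x), 0, sigma))
  }
  x + noise
}

#' Simulate a fluorescence titration series
#'
#' Evaluates the ligand-depletion isotherm ([binding_curve()]) on a ligand
#' grid and adds Gaussian noise. Defaults mirror the study design: a fixed
#' 3 uM receptor titrated with peptide over 0-30 uM. With `sigma = 0` the
#' output equals the forward model pointwise; identical seeds give
#' identical series.
#'
#' @param kd,f0,dfmax Isotherm parameters (Kd in uM).
#' @param pt Fixed receptor concentration, uM.
#' @param lt Ligand concentration grid, uM.
#' @param sigma Gaussian noise standard deviation (signal units).
#' @param seed Optional integer seed.
#' @return A tibble with `ligand_total` (uM) and `fluorescence`.
#' @export
simulate_titration <- function(kd, f0, dfmax, pt = 3,
                               lt = seq(0, 30, length.out = 16),
                               sigma = 0, seed = NULL) {
  f <- binding_curve(lt, pt, kd, f0, dfmax)
  tibble(ligand_total = lt, fluorescence = .add_noise(f, sigma, seed))
}

#' Simulate a single-site ITC isotherm
#'
#' Forward-models the per-injection ligand-normalized heats
#' ([injection_heats()]) under a protocol and adds Gaussian noise. With
#' `sigma = 0` the output equals the forward model exactly.
#'
#' @param protocol An [itc_protocol()] (default: 19 x 2 uL, 10 uM cell,
#'   100 uM syringe).
#' @param ka Association constant, M-1.
#' @param dh Binding enthalpy, kcal mol-1.
#' @param n Apparent stoichiometry.
#' @param qd Background heat, kcal mol-1 of injectant.
#' @param sigma Gaussian noise sd, kcal mol-1 of injectant.
#' @param seed Optional integer seed.
#' @return A tibble with `injection`, `molar_ratio`, `heat`.
#' @export
simulate_itc <- function(protocol = itc_protocol(), ka, dh, n = 1, qd = 0,
                         sigma = 0, seed = NULL) {
  iso <- injection_heats(protocol, ka, dh, n, qd)
  iso$heat <- .add_noise(iso$heat, sigma, seed)
  iso
}

#' Simulate a thermogram of injection power peaks
#'
#' Renders an isotherm as a synthetic thermal-power trace: each injection
#' contributes an exponentially decaying power peak (time constant `tau`)
#' whose time integral equals that injection's ligand-normalized heat, so
#' that numerical re-integration recovers the isotherm. Power is expressed
#' in kcal per mol of injectant per second (a simulator convention that
#' keeps the integral directly comparable to the isotherm).
#'
#' @param protocol An [itc_protocol()].
#' @param heats Numeric vector of per-injection heats (kcal mol-1), e.g.
#'   the `heat` column of [simulate_itc()].
#' @param tau Peak decay time constant, s.
#' @param dt Sampling interval, s.
#' @param spacing Time between injections, s.
#' @return A tibble with `time` (s) and `power`.
#' @export
simulate_thermogram <- function(protocol, heats, tau = 4, dt = 0.25,
                                spacing = 150) {
  stopifnot(length(heats) == length(protocol$injection_volumes), tau > 0, dt > 0)
  t_inj <- (seq_along(heats) - 1) * spacing
  time <- seq(0, length(heats) * spacing - dt, by = dt)
  power <- numeric(length(time))
  for (k in seq_along(heats)) {
    after <- time >= t_inj[k]
    power[after] <- power[after] +
      heats[k] / tau * exp(-(time[after] - t_inj[k]) / tau)
  }
  tibble(time = time, power = power)
}

#' Integrate a thermogram back into per-injection heats
#'
#' Trapezoidal integration of the power trace over each inter-injection
#' window, mirroring how binding isotherms are built from recorded
#' thermograms.
#'
#' @param thermogram A tibble with `time` and `power` from
#'   [simulate_thermogram()].
#' @param protocol The matching [itc_protocol()].
#' @param spacing Time between injections, s.
#' @return A tibble with `injection` and `heat`.
#' @export
integrate_thermogram <- function(thermogram, protocol, spacing = 150) {
  n_inj <- length(protocol$injection_volumes)
  heats <- vapply(seq_len(n_inj), function(k) {
    lo <- (k - 1) * spacing
    hi <- k * spacing
    # half-open window: the sample at `hi` already contains the next
    # injection's power jump and belongs to the next window
    keep <- thermogram$time >= lo & thermogram$time < hi
    t <- thermogram$time[keep]
    p <- thermogram$power[keep]
    sum(diff(t) * (head(p, -1) + tail(p, -1)) / 2)
  }, numeric(1))
  tibble(injection = seq_len(n_inj), heat = heats)
}

#' Simulate biolayer-interferometry sensorgrams
#'
#' Generates one reference-subtracted trace per analyte concentration under
#' a two-state 1:1 Langmuir model: the association phase follows
#' [association_model()] with kobs = kon c + koff and equilibrium response
#' Req = Rmax c / (c + Kd), Kd = koff/kon; the dissociation phase follows
#' [dissociation_model()] starting from the noiseless association end level
#' so traces are continuous at every segment boundary. The load segment
#' rises exponentially and the second baseline ramps linearly back to zero
#' by the association start (the traces are reference-subtracted, so the
#' association response starts from zero as the model requires).
#'
#' @param kon Association rate, uM-1 s-1.
#' @param koff Dissociation rate, s-1.
#' @param rmax Maximal (saturating) response.
#' @param concentrations Analyte concentrations, uM (default 1-10 uM).
#' @param schedule A [bli_schedule()].
#' @param drift_assoc,drift_dissoc Linear drift magnitudes per segment
#'   (response units per s), subtracted as in the fitting models.
#' @param sigma Gaussian noise sd (response units).
#' @param seed Optional integer seed.
#' @param dt Sampling interval, s.
#' @return A tibble with `time`, `response`, `concentration`, `segment`.
#' @export
simulate_bli <- function(kon, koff, rmax = 1,
                         concentrations = c(1, 2, 5, 10),
                         schedule = bli_schedule(),
                         drift_assoc = 0, drift_dissoc = 0,
                         sigma = 0, seed = NULL, dt = 0.2) {
  if (any(concentrations <= 0)) abort("concentrations must be positive")
  stopifnot(kon > 0, koff >= 0, rmax > 0)
  kd <- koff / kon
  aw <- .segment_window(schedule, "association")
  dw <- .segment_window(schedule, "dissociation")
  lw <- .segment_window(schedule, "load")
  bw2 <- .segment_window(schedule, "baseline2")
  t_all <- seq(min(schedule$start), max(schedule$end), by = dt)
  seg_of <- function(t) {
    schedule$name[findInterval(pmin(t, max(schedule$end) - 1e-9), schedule$start)]
  }
  load_end <- rmax * (1 - exp(-(lw[["end"]] - lw[["start"]]) / 20))
  traces <- purrr::imap(setNames(concentrations, concentrations), function(conc, nm) {
    kobs <- kon * conc + koff
    req <- rmax * conc / (conc + kd)
    seg <- seg_of(t_all)
    r <- numeric(length(t_all))
    r[seg == "baseline1"] <- 0
    il <- seg == "load"
    r[il] <- rmax * (1 - exp(-(t_all[il] - lw[["start"]]) / 20))
    ib <- seg == "baseline2"
    # linear ramp from the load end level back to zero at the association start
    r[ib] <- load_end * (bw2[["end"]] - t_all[ib]) / (bw2[["end"]] - bw2[["start"]])
    ia <- seg == "association"
    r[ia] <- association_model(t_all[ia], req, kobs, drift_assoc, aw[["start"]])
    r1 <- association_model(dw[["start"]], req, kobs, drift_assoc, aw[["start"]])
    id <- seg == "dissociation" | t_all >= dw[["start"]]
    r[id] <- dissociation_model(t_all[id], r1, koff, drift_dissoc, dw[["start"]])
    tibble(time = t_all, response = r, concentration = conc, segment = seg)
  })
  out <- dplyr::bind_rows(traces)
  out$response <- .add_noise(out$response, sigma, seed)
  out
}

#' Simulate pulsed-field-gradient diffusion decays
#'
#' Mono-exponential Stejskal-Tanner decays for a solute and a paired
#' dioxane internal-reference trace, on a shared gradient grid with shared
#' acquisition constants. The default reference diffusion coefficient gives
#' the solute/reference ratio observed for a ~3.7 kDa disordered peptide
#' (reference-based Rh near 14 Angstrom at the default solute D).
#'
#' @param d Solute diffusion coefficient, cm2 s-1.
#' @param d_reference Dioxane diffusion coefficient, cm2 s-1.
#' @param gradients Gradient strength grid, G cm-1.
#' @param gamma,delta,big_delta Acquisition constants as in [fit_decay()].
#' @param i0 Intensity at zero gradient.
#' @param sigma Gaussian noise sd (intensity units).
#' @param seed Optional integer seed.
#' @return A tibble with `species` ("solute"/"dioxane"), `gradient`,
#'   `intensity`.
#' @export
simulate_dosy <- function(d = 9.3e-7, d_reference = 6.141e-6,
                          gradients = seq(2, 45, length.out = 16),
                          gamma = 26752, delta = 0.004, big_delta = 0.1,
                          i0 = 1, sigma = 0, seed = NULL) {
  stopifnot(d > 0, d_reference > 0, length(gradients) >= 3)
  b <- (gamma * gradients * delta)^2 * (big_delta - delta / 3)
  out <- dplyr::bind_rows(
    tibble(species = "solute", gradient = gradients, intensity = i0 * exp(-d * b)),
    tibble(species = "dioxane", gradient = gradients,
           intensity = i0 * exp(-d_reference * b))
  )
  out$intensity <- .add_noise(out$intensity, sigma, seed)
  out
}

#' Simulate an Halpha chemical-shift table
#'
#' Draws observed shifts around the sequence-corrected random-coil
#' reference. In `"coil"` mode, `delta_obs = delta_rc + N(0, sigma)`; in
#' `"helical-segment"` mode a constant upfield bias is additionally
#' subtracted over a chosen positional segment, emulating nascent helical
#' structure.
#'
#' @param sequence One-letter sequence string.
#' @param start_residue Numbering of the first residue.
#' @param mode `"coil"` or `"helical-segment"`.
#' @param bias Bias magnitude in ppm (subtracted on the segment).
#' @param segment Integer positions (in `start_residue` numbering) carrying
#'   the bias; required in helical mode.
#' @param sigma Gaussian noise sd, ppm.
#' @param seed Optional integer seed.
#' @param model A [random_coil_model()].
#' @return A shift-table tibble with `position`, `residue`, `atom`,
#'   `delta_obs`.
#' @export
simulate_shift_table <- function(sequence, start_residue = 1L,
                                 mode = c("coil", "helical-segment"),
                                 bias = 0.3, segment = NULL,
                                 sigma = 0.02, seed = NULL,
                                 model = random_coil_model()) {
  mode <- match.arg(mode)
  rc <- random_coil_shifts(sequence, start_residue, "HA", model)
  delta <- rc$delta_rc
  if (mode == "helical-segment") {
    if (is.null(segment)) abort("helical-segment mode needs a `segment` of positions")
    delta[rc$position %in% segment] <- delta[rc$position %in% segment] - bias
  }
  tibble(
    position = rc$position, residue = rc$residue, atom = "HA",
    delta_obs = .add_noise(delta, sigma, seed)
  )
}
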