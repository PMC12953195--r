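#' Default biolayer-interferometry segment schedule
#'
#' Contiguous, non-overlapping sensorgram segments: 30 s initial baseline,
#' 120 s of loading the importin onto the biosensor, 30 s of second
#' baseline, 120 s of peptide association (starting at t0 = 180 s) and
#' 120 s of dissociation (starting at t0 = 300 s).
#'
#' @param segments Optional tibble with columns `name`, `start`, `duration`
#'   (s) to override the default.
#' @return A tibble of class `bli_schedule` with `name`, `start`,
#'   `duration`, `end`.
#' @export
bli_schedule <- function(segments = NULL) {
  segments <- segments %||% tibble(
    name = c("baseline1", "load", "baseline2", "association", "dissociation"),
    start = c(0, 30, 150, 180, 300),
    duration = c(30, 120, 30, 120, 120)
  )
  segments$end <- segments$start + segments$duration
  if (any(abs(head(segments$end, -1) - tail(segments$start, -1)) > 1e-9)) {
    abort("schedule segments must be contiguous and non-overlapping")
  }
  structure(as_tibble(segments), class = c("bli_schedule", class(tibble())))
}

.segment_window <- function(schedule, name) {
  row <- schedule[schedule$name == name, , drop = FALSE]
  if (nrow(row) != 1) abort(sprintf("schedule has no '%s' segment", name))
  c(start = row$start, end = row$end)
}

#' Association-phase response model with linear drift
#'
#' \deqn{R(t) = R_{eq} - R_{eq} e^{-k_{obs}(t - t_0)} - R'_{eq}(t - t_0)}
#' so that R(t0) = 0 by construction and, with zero drift, R approaches the
#' steady-state response Req as t grows.
#'
#' @param t Time, s (>= t0).
#' @param req Steady-state (equilibrium) response.
#' @param kobs Observed rate constant, s-1.
#' @param drift Linear drift magnitude R'eq (response units per s),
#'   subtracted.
#' @param t0 Association start time, s (default 180).
#' @return Response values.
#' @export
association_model <- function(t, req, kobs, drift = 0, t0 = 180) {
  if (any(t < t0)) abort("association model is defined for t >= t0")
  req - req * exp(-kobs * (t - t0)) - drift * (t - t0)
}

#' Dissociation-phase response model with linear drift
#'
#' \deqn{R(t) = R_1 e^{-k_{off}(t - t_0)} - R''_{eq}(t - t_0)}
#' with R1 the response level when dissociation starts, so R(t0) = R1.
#'
#' @param t Time, s (>= t0).
#' @param r1 Response at dissociation start.
#' @param koff Dissociation rate constant, s-1.
#' @param drift Linear drift magnitude R''eq, subtracted.
#' @param t0 Dissociation start time, s (default 300).
#' @return Response values.
#' @export
dissociation_model <- function(t, r1, koff, drift = 0, t0 = 300) {
  if (any(t < t0)) abort("dissociation model is defined for t >= t0")
  r1 * exp(-koff * (t - t0)) - drift * (t - t0)
}

.pull_segment <- function(data, time, response, window) {
  t <- dplyr::pull(data, {{ time }})
  r <- dplyr::pull(data, {{ response }})
  keep <- t >= window[["start"]] & t <= window[["end"]]
  if (sum(keep) < 20) abort("segment contains fewer than 20 samples")
  if (any(diff(t[keep]) <= 0)) abort("time must be strictly increasing")
  tibble(t = t[keep], r = r[keep])
}

#' Fit the association phase of a sensorgram
#'
#' Least-squares fit of the drift-corrected single-exponential association
#' model on the association segment of the schedule. Uncertainties from the
#' covariance matrix; non-convergence or a non-positive fitted kobs fails
#' explicitly.
#'
#' @param data Sensorgram data frame.
#' @param time,response Columns (tidy-eval) with time (s) and response.
#' @param schedule A [bli_schedule()]; the association window and t0 come
#'   from it.
#' @return Object of class `bli_assoc_fit` with `req`, `kobs`, `drift`,
#'   standard errors and the fit.
#' @export
fit_association <- function(data, time = time, response = response,
                            schedule = bli_schedule()) {
  win <- .segment_window(schedule, "association")
  seg <- .pull_segment(data, {{ time }}, {{ response }}, win)
  t0 <- win[["start"]]
  req0 <- mean(tail(seg$r, 10))
  if (abs(req0) < 1e-12) req0 <- max(abs(seg$r)) * sign(sum(seg$r) + 1e-300)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ association_model(t, req, kobs, drift, t0 = t0), data = seg,
      start = list(req = req0, kobs = 0.05, drift = 0),
      lower = c(req = -Inf, kobs = 1e-6, drift = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) abort(paste("association fit did not converge:",
                                    conditionMessage(e)))
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  rel_se <- se[["kobs"]] / est[["kobs"]]
  if (!is.finite(rel_se) || rel_se > 1) {
    abort("association fit is unreliable: kobs is not resolved above noise")
  }
  structure(
    list(req = unname(est[["req"]]), sigma_req = unname(se[["req"]]),
         kobs = unname(est[["kobs"]]), sigma_kobs = unname(se[["kobs"]]),
         drift = unname(est[["drift"]]), sigma_drift = unname(se[["drift"]]),
         t0 = t0, n = nrow(seg), data = seg, fit = fit),
    class = "bli_assoc_fit"
  )
}

#' Fit the dissociation phase of a sensorgram
#'
#' Least-squares fit of the drift-corrected exponential dissociation model
#' on the dissociation segment of the schedule.
#'
#' @inheritParams fit_association
#' @return Object of class `bli_dissoc_fit` with `r1`, `koff`, `drift`,
#'   standard errors and the fit.
#' @export
fit_dissociation <- function(data, time = time, response = response,
                             schedule = bli_schedule()) {
  win <- .segment_window(schedule, "dissociation")
  seg <- .pull_segment(data, {{ time }}, {{ response }}, win)
  t0 <- win[["start"]]
  r10 <- seg$r[1]
  if (abs(r10) < 1e-12) r10 <- max(abs(seg$r), 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ dissociation_model(t, r1, koff, drift, t0 = t0), data = seg,
      start = list(r1 = r10, koff = 0.05, drift = 0),
      lower = c(r1 = -Inf, koff = 0, drift = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) abort(paste("dissociation fit did not converge:",
                                    conditionMessage(e)))
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  rel_se <- se[["r1"]] / abs(est[["r1"]])
  if (!is.finite(rel_se) || rel_se > 1) {
    abort("dissociation fit is unreliable: amplitude not resolved above noise")
  }
  structure(
    list(r1 = unname(est[["r1"]]), sigma_r1 = unname(se[["r1"]]),
         koff = unname(est[["koff"]]), sigma_koff = unname(se[["koff"]]),
         drift = unname(est[["drift"]]), sigma_drift = unname(se[["drift"]]),
         t0 = t0, n = nrow(seg), data = seg, fit = fit),
    class = "bli_dissoc_fit"
  )
}

#' Pseudo-first-order analysis of observed rates
#'
#' Ordinary linear regression of kobs against analyte concentration:
#' \eqn{k_{obs} = k_{on}[NLSpeptide] + k_{off}}. The slope is kon
#' (uM-1 s-1) and the intercept koff (s-1), with standard errors from the
#' regression. A negative fitted intercept is reported as-is with a
#' warning; it is floored at zero only when deriving Kd downstream.
#'
#' @param kobs Observed rate constants, s-1.
#' @param concentrations Analyte concentrations, uM (>= 3 distinct values).
#' @return Object of class `pfo_fit` with `kon`, `koff`, standard errors,
#'   `koff_floored` and the `lm` fit.
#' @export
#' @examples
#' pseudo_first_order(c(0.129, 0.168, 0.285, 0.48), c(1, 2, 5, 10))
pseudo_first_order <- function(kobs, concentrations) {
  if (length(kobs) != length(concentrations)) {
    abort("kobs and concentrations must have equal length")
  }
  if (length(unique(concentrations)) < 3) {
    abort("need at least 3 distinct concentrations for the pseudo-first-order plot")
  }
  fit <- lm(kobs ~ concentrations)
  est <- coef(fit)
  # vcov warns on numerically perfect fits; zero standard errors are valid here
  se <- suppressWarnings(sqrt(diag(vcov(fit))))
  koff <- unname(est[1]); kon <- unname(est[2])
  koff_floored <- koff
  if (koff < 0) {
    warn("fitted koff (intercept) is negative; floored at 0 for derived Kd only")
    koff_floored <- 0
  }
  structure(
    list(kon = kon, sigma_kon = unname(se[2]),
         koff = koff, sigma_koff = unname(se[1]),
         koff_floored = koff_floored,
         n = length(kobs),
         data = tibble(concentration = concentrations, kobs = kobs),
         fit = fit),
    class = "pfo_fit"
  )
}

#' @export
print.pfo_fit <- function(x, ...) {
  cat(sprintf("Pseudo-first-order fit (n = %d)\n", x$n))
  cat(sprintf("  kon  = %.3g +/- %.2g uM-1 s-1\n", x$kon, x$sigma_kon))
  cat(sprintf("  koff = %.3g +/- %.2g s-1\n", x$koff, x$sigma_koff))
  invisible(x)
}

#' Equilibrium dissociation constant from kinetic rates
#'
#' Kd = koff/kon under the two-state assumption, with first-order
#' quadrature error propagation
#' \eqn{\sigma_{K_d} = K_d\sqrt{(\sigma_{k_{on}}/k_{on})^2 +
#' (\sigma_{k_{off}}/k_{off})^2}}.
#'
#' @param kon Association rate, uM-1 s-1 (> 0).
#' @param koff Dissociation rate, s-1 (>= 0).
#' @param sigma_kon,sigma_koff Rate uncertainties.
#' @return A tibble with `kd` (uM), `sigma_kd` and `two_state` flag.
#' @export
#' @examples
#' kd_from_rates(0.039, 0.09) # 2.3 uM
kd_from_rates <- function(kon, koff, sigma_kon = 0, sigma_koff = 0) {
  if (any(kon <= 0)) abort("kon must be positive")
  if (any(koff < 0)) abort("koff must be non-negative")
  kd <- koff / kon
  rel <- sqrt((sigma_kon / kon)^2 +
                ifelse(koff > 0, (sigma_koff / koff)^2, 0))
  tibble(kd = kd, sigma_kd = kd * rel, two_state = TRUE)
}

#' Full kinetic analysis of a set of sensorgrams
#'
#' Fits the association phase of each trace, regresses the observed rates
#' on concentration (pseudo-first-order plot), fits each dissociation phase,
#' and derives Kd = koff/kon with propagated errors. kon and koff are taken
#' from the regression slope and intercept; the mean of the per-trace
#' dissociation fits is reported alongside as a cross-check.
#'
#' @param sensorgrams A data frame with columns `time`, `response`,
#'   `concentration` (uM), as produced by [simulate_bli()].
#' @param schedule A [bli_schedule()].
#' @return Object of class `bli_kinetics`: `kon`, `koff`, `kd` (uM) with
#'   uncertainties, per-trace tibble `traces`, the `pfo_fit`, and the
#'   two-state assumption flag.
#' @export
#' @examples
#' sg <- simulate_bli(kon = 0.039, koff = 0.09, sigma = 0)
#' fit_kinetics(sg)
fit_kinetics <- function(sensorgrams, schedule = bli_schedule()) {
  split_traces <- split(sensorgrams, sensorgrams$concentration)
  per <- purrr::map(split_traces, function(tr) {
    af <- fit_association(tr, schedule = schedule)
    df <- fit_dissociation(tr, schedule = schedule)
    tibble(
      concentration = tr$concentration[1],
      kobs = af$kobs, sigma_kobs = af$sigma_kobs, req = af$req,
      koff_trace = df$koff, sigma_koff_trace = df$sigma_koff, r1 = df$r1
    )
  }) |> dplyr::bind_rows() |> dplyr::arrange(.data$concentration)
  pfo <- pseudo_first_order(per$kobs, per$concentration)
  kd <- kd_from_rates(pfo$kon, pfo$koff_floored,
                      pfo$sigma_kon, pfo$sigma_koff)
  structure(
    list(kon = pfo$kon, sigma_kon = pfo$sigma_kon,
         koff = pfo$koff, sigma_koff = pfo$sigma_koff,
         koff_dissociation = mean(per$koff_trace),
         kd = kd$kd, sigma_kd = kd$sigma_kd,
         two_state = TRUE, traces = per, pfo = pfo),
    class = "bli_kinetics"
  )
}

#' @export
print.bli_kinetics <- function(x, ...) {
  cat("BLI kinetic analysis (two-state assumption)\n")
  cat(sprintf("  kon  = %.3g +/- %.2g uM-1 s-1\n", x$kon, x$sigma_kon))
  cat(sprintf("  koff = %.3g +/- %.2g s-1 (per-trace dissociation mean %.3g)\n",
              x$koff, x$sigma_koff, x$koff_dissociation))
  cat(sprintf("  Kd   = koff/kon = %.3g +/- %.2g uM\n", x$kd, x$sigma_kd))
  invisible(x)
}
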