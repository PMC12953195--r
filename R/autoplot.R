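#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line labs
NULL

#' @export
ggplot2::autoplot

#' Plot a titration fit
#'
#' Observed points with the fitted ligand-depletion isotherm overlaid on a
#' fine ligand grid.
#'
#' @param object A `fluor_fit`.
#' @param ... Unused.
#' @method autoplot fluor_fit
#' @export
autoplot.fluor_fit <- function(object, ...) {
  grid <- tibble(
    lt = seq(min(object$data$lt), max(object$data$lt), length.out = 200)
  )
  grid$f <- binding_curve(grid$lt, object$pt, object$kd, object$f0, object$dfmax)
  ggplot(object$data, aes(x = .data$lt, y = .data$f)) +
    geom_point() +
    geom_line(data = grid, colour = "steelblue") +
    labs(x = "[NLS peptide] total (uM)", y = "fluorescence",
         title = sprintf("Ligand-depletion fit: Kd = %.3g uM", object$kd))
}

#' Plot an ITC isotherm fit
#'
#' Ligand-normalized heats per injection against molar ratio, with the
#' fitted single-site model.
#'
#' @param object An `itc_fit`.
#' @param protocol The [itc_protocol()] used for the fit (for the model
#'   curve and molar ratios).
#' @param ... Unused.
#' @method autoplot itc_fit
#' @export
autoplot.itc_fit <- function(object, protocol = itc_protocol(), ...) {
  model <- injection_heats(protocol, object$ka, object$dh, object$n, object$qd)
  obs <- dplyr::left_join(object$data,
                          model[, c("injection", "molar_ratio")],
                          by = c(j = "injection"))
  ggplot(obs, aes(x = .data$molar_ratio, y = .data$q)) +
    geom_point() +
    geom_line(data = model, aes(x = .data$molar_ratio, y = .data$heat),
              colour = "firebrick") +
    labs(x = "molar ratio [L]/[P]", y = "Q (kcal/mol of injectant)",
         title = sprintf("Single-site ITC fit: Kd = %.3g uM, dH = %.3g kcal/mol",
                         object$kd, object$dh))
}

#' Plot a diffusion decay fit
#'
#' @param object A `dosy_fit`.
#' @param ... Unused.
#' @method autoplot dosy_fit
#' @export
autoplot.dosy_fit <- function(object, ...) {
  grid <- tibble(b = seq(0, max(object$data$b), length.out = 200))
  grid$intensity <- object$i0 * exp(-object$d * grid$b)
  ggplot(object$data, aes(x = .data$b, y = .data$intensity)) +
    geom_point() +
    geom_line(data = grid, colour = "darkgreen") +
    labs(x = "b = (gamma g delta)^2 (Delta - delta/3) (s cm-2)",
         y = "intensity",
         title = sprintf("PFG decay: D = %.3g cm2/s", object$d))
}

#' Plot a pseudo-first-order analysis
#'
#' kobs against analyte concentration with the fitted line whose slope is
#' kon and intercept koff.
#'
#' @param object A `bli_kinetics` result.
#' @param ... Unused.
#' @method autoplot bli_kinetics
#' @export
autoplot.bli_kinetics <- function(object, ...) {
  df <- object$traces
  grid <- tibble(concentration = seq(0, max(df$concentration), length.out = 50))
  grid$kobs <- object$kon * grid$concentration + object$koff
  ggplot(df, aes(x = .data$concentration, y = .data$kobs)) +
    geom_point() +
    geom_line(data = grid, colour = "purple") +
    labs(x = "[NLS peptide] (uM)", y = "kobs (s-1)",
         title = sprintf("Pseudo-first-order: kon = %.3g uM-1 s-1, koff = %.3g s-1",
                         object$kon, object$koff))
}

#' Plot sensorgrams by concentration
#'
#' @param sensorgrams Output of [simulate_bli()] (or any tibble with
#'   `time`, `response`, `concentration`).
#' @return A ggplot object.
#' @export
plot_sensorgrams <- function(sensorgrams) {
  ggplot(sensorgrams,
         aes(x = .data$time, y = .data$response,
             colour = factor(.data$concentration))) +
    geom_line() +
    labs(x = "time (s)", y = "response", colour = "[peptide] (uM)")
}
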