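#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @title Broom-style tidiers for fitted objects
#' @description `tidy()` returns one row per fitted parameter with estimate
#'   and standard error; `glance()` returns a one-row model summary.
#' @param x A fitted object (`fluor_fit`, `itc_fit`, `dosy_fit`,
#'   `bli_assoc_fit`, `bli_dissoc_fit`, `pfo_fit`, `bli_kinetics`).
#' @param ... Unused.
#' @method tidy fluor_fit
#' @export
tidy.fluor_fit <- function(x, ...) {
  tibble(
    term = c("kd", "f0", "dfmax"),
    estimate = c(x$kd, x$f0, x$dfmax),
    std.error = c(x$sigma_kd, x$sigma_f0, x$sigma_dfmax)
  )
}

#' @rdname tidiers
#' @method glance fluor_fit
#' @export
glance.fluor_fit <- function(x, ...) {
  tibble(kd = x$kd, sigma_kd = x$sigma_kd, identifiable = x$identifiable,
         residual_norm = x$residual_norm, nobs = x$n)
}

#' @rdname tidiers
#' @method tidy itc_fit
#' @export
tidy.itc_fit <- function(x, ...) {
  tibble(
    term = c("ka", "kd", "dh", "n", "qd"),
    estimate = c(x$ka, x$kd, x$dh, x$n, x$qd),
    std.error = c(x$sigma_ka, x$sigma_kd, x$sigma_dh, x$sigma_n, x$sigma_qd)
  )
}

#' @rdname tidiers
#' @method glance itc_fit
#' @export
glance.itc_fit <- function(x, ...) {
  tibble(ka = x$ka, kd = x$kd, dh = x$dh, n = x$n, qd = x$qd,
         dg = x$profile$dg, minus_tds = x$profile$minus_tds,
         entropically_driven = x$profile$entropically_driven,
         c_value = x$c_value, residual_norm = x$residual_norm,
         nobs = x$n_injections)
}

#' @rdname tidiers
#' @method tidy dosy_fit
#' @export
tidy.dosy_fit <- function(x, ...) {
  tibble(term = c("d", "i0"), estimate = c(x$d, x$i0),
         std.error = c(x$sigma_d, NA_real_))
}

#' @rdname tidiers
#' @method glance dosy_fit
#' @export
glance.dosy_fit <- function(x, ...) {
  tibble(d = x$d, sigma_d = x$sigma_d, nobs = x$n)
}

#' @rdname tidiers
#' @method tidy bli_assoc_fit
#' @export
tidy.bli_assoc_fit <- function(x, ...) {
  tibble(term = c("req", "kobs", "drift"),
         estimate = c(x$req, x$kobs, x$drift),
         std.error = c(x$sigma_req, x$sigma_kobs, x$sigma_drift))
}

#' @rdname tidiers
#' @method tidy bli_dissoc_fit
#' @export
tidy.bli_dissoc_fit <- function(x, ...) {
  tibble(term = c("r1", "koff", "drift"),
         estimate = c(x$r1, x$koff, x$drift),
         std.error = c(x$sigma_r1, x$sigma_koff, x$sigma_drift))
}

#' @rdname tidiers
#' @method tidy pfo_fit
#' @export
tidy.pfo_fit <- function(x, ...) {
  tibble(term = c("kon", "koff"), estimate = c(x$kon, x$koff),
         std.error = c(x$sigma_kon, x$sigma_koff))
}

#' @rdname tidiers
#' @method tidy bli_kinetics
#' @export
tidy.bli_kinetics <- function(x, ...) {
  tibble(term = c("kon", "koff", "kd"),
         estimate = c(x$kon, x$koff, x$kd),
         std.error = c(x$sigma_kon, x$sigma_koff, x$sigma_kd))
}

#' @rdname tidiers
#' @method glance bli_kinetics
#' @export
glance.bli_kinetics <- function(x, ...) {
  tibble(kon = x$kon, koff = x$koff, kd = x$kd, sigma_kd = x$sigma_kd,
         koff_dissociation = x$koff_dissociation, two_state = x$two_state,
         n_traces = nrow(x$traces))
}
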