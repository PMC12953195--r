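# Independent oracles used to cross-check closed-form model code.

# Iterative 1:1 equilibrium solver: find [PL] such that
# Ka (nPT - PL)(LT - PL) = PL, concentrations in uM, Ka in M-1.
# Root-finding route, independent of the quadratic closed form.
oracle_complex_uM <- function(pt, lt, ka, n = 1) {
  p <- n * pt * 1e-6
  l <- lt * 1e-6
  upper <- min(p, l)
  if (upper == 0) return(0)
  f <- function(x) ka * (p - x) * (l - x) - x
  stats::uniroot(f, c(0, upper), tol = 1e-18)$root * 1e6
}

# Brute-force ITC simulator: re-equilibrates total masses after each
# injection and differences the complex content of the cell.
oracle_injection_heats <- function(protocol, ka, dh, n = 1, qd = 0) {
  v0 <- protocol$v0
  vols <- protocol$injection_volumes
  lt <- 0
  pt <- protocol$cell_protein
  pl_prev <- 0
  q <- numeric(length(vols))
  for (j in seq_along(vols)) {
    dil <- 1 - vols[j] / v0
    lt <- lt * dil + protocol$syringe_ligand * vols[j] / v0
    pt <- pt * dil
    pl <- oracle_complex_uM(pt, lt, ka, n)
    q[j] <- v0 * dh * (pl - pl_prev * dil) / (vols[j] * protocol$syringe_ligand) + qd
    pl_prev <- pl
  }
  q
}

# Gaussian emission spectrum on a wavelength grid.
gaussian_spectrum <- function(center, width = 20, amplitude = 1,
                              grid = seq(280, 420, by = 1)) {
  tibble::tibble(
    wavelength = grid,
    intensity = amplitude * exp(-(grid - center)^2 / (2 * width^2))
  )
}
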