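#' Random-coil chemical-shift reference model
#'
#' Loads the packaged random-coil Halpha reference shifts and
#' neighbor-correction terms. The values ship as plain CSV data, not
#' hard-coded constants, so an alternative coil scale can be swapped in by
#' pointing `base_path`/`corrections_path` at other files with the same
#' columns.
#'
#' @param base_path CSV with columns `residue`, `atom`, `shift_ppm`.
#' @param corrections_path CSV with columns `offset` (relative position of
#'   the neighbor, e.g. 1 for the following residue), `neighbor_residue`,
#'   `atom`, `correction_ppm`. Corrections are added to the base shift of
#'   residue i when the residue at i + offset matches.
#' @return A list of class `random_coil_model` with elements `base` and
#'   `corrections` (tibbles).
#' @export
random_coil_model <- function(base_path = NULL, corrections_path = NULL) {
  base_path <- base_path %||%
    system.file("extdata", "halpha_random_coil.csv", package = "nlsbind")
  corrections_path <- corrections_path %||%
    system.file("extdata", "halpha_neighbor_corrections.csv", package = "nlsbind")
  base <- as_tibble(utils::read.csv(base_path, stringsAsFactors = FALSE))
  corrections <- as_tibble(utils::read.csv(corrections_path, stringsAsFactors = FALSE))
  stopifnot(all(c("residue", "atom", "shift_ppm") %in% names(base)))
  if (any(abs(corrections$correction_ppm) >= 1)) {
    abort("neighbor corrections must be bounded (|corr| < 1 ppm)")
  }
  structure(list(base = base, corrections = corrections),
            class = "random_coil_model")
}

#' Sequence-corrected random-coil shift for every residue of a sequence
#'
#' @param sequence One-letter sequence string.
#' @param start_residue Numbering of the first residue.
#' @param atom Atom label (default `"HA"`).
#' @param model A [random_coil_model()].
#' @return A tibble `position`, `residue`, `delta_rc` (NA where the model
#'   has no entry).
#' @export
random_coil_shifts <- function(sequence, start_residue = 1L, atom = "HA",
                               model = random_coil_model()) {
  res <- strsplit(sequence, "")[[1]]
  base <- model$base[model$base$atom == atom, , drop = FALSE]
  lookup <- setNames(base$shift_ppm, base$residue)
  delta <- unname(lookup[res])
  corr <- model$corrections[model$corrections$atom == atom, , drop = FALSE]
  if (nrow(corr)) {
    for (k in seq_len(nrow(corr))) {
      nb <- seq_along(res) + corr$offset[k]
      hit <- nb >= 1 & nb <= length(res)
      hit[hit] <- res[nb[hit]] == corr$neighbor_residue[k]
      delta[hit] <- delta[hit] + corr$correction_ppm[k]
    }
  }
  tibble(position = start_residue + seq_along(res) - 1L,
         residue = res, delta_rc = delta)
}

#' Per-residue conformational shifts of Halpha protons
#'
#' Computes \eqn{\Delta\delta = \delta_{obs} - \delta_{rc}} where the
#' random-coil reference is corrected for neighboring-residue effects.
#' Residues whose observed type disagrees with the sequence raise an error;
#' residues lacking a reference entry are excluded with a warning.
#'
#' @param shifts A data frame of observed shifts with columns `position`,
#'   `residue`, `atom`, `delta_obs` (ppm from TSP).
#' @param sequence One-letter sequence string covering the positions.
#' @param start_residue Numbering of the first sequence residue.
#' @param atom Atom label to analyze (default `"HA"`).
#' @param model A [random_coil_model()].
#' @return A tibble `position`, `residue`, `delta_obs`, `delta_rc`,
#'   `delta_delta` (ppm), with attribute `n_excluded`.
#' @export
conformational_shifts <- function(shifts, sequence, start_residue = 1L,
                                  atom = "HA", model = random_coil_model()) {
  stopifnot(all(c("position", "residue", "atom", "delta_obs") %in% names(shifts)))
  obs <- shifts[shifts$atom == atom, , drop = FALSE]
  if (nrow(obs) == 0) abort("no observed shifts for the requested atom")
  if (any(obs$delta_obs < 0 | obs$delta_obs > 12)) {
    abort("observed shifts outside the plausible 0-12 ppm range")
  }
  rc <- random_coil_shifts(sequence, start_residue, atom, model)
  merged <- dplyr::inner_join(obs, rc, by = "position", suffix = c("", "_seq"))
  if (nrow(merged) < nrow(obs)) {
    missing <- setdiff(obs$position, rc$position)
    abort(sprintf("positions outside the peptide span: %s",
                  paste(missing, collapse = ", ")))
  }
  bad <- merged$residue != merged$residue_seq
  if (any(bad)) {
    abort(sprintf(
      "residue mismatch at position %d: table says %s, sequence says %s",
      merged$position[bad][1], merged$residue[bad][1], merged$residue_seq[bad][1]
    ))
  }
  no_ref <- is.na(merged$delta_rc)
  if (any(no_ref)) {
    warn(sprintf("%d residue(s) lack a random-coil reference and were excluded",
                 sum(no_ref)))
  }
  out <- merged[!no_ref, , drop = FALSE]
  out <- tibble(
    position = out$position, residue = out$residue,
    delta_obs = out$delta_obs, delta_rc = out$delta_rc,
    delta_delta = out$delta_obs - out$delta_rc
  )
  attr(out, "n_excluded") <- sum(no_ref)
  out
}

#' Classify peptide disorder from conformational shifts
#'
#' A peptide is classified random-coil when every assigned residue has
#' |delta-delta| at or below the threshold (0.1 ppm, inclusive at the
#' boundary); otherwise it is structured and the offending residues are
#' listed. Evaluation is strict over all residues.
#'
#' @param deltas Output of [conformational_shifts()] (needs columns
#'   `position`, `residue`, `delta_delta`).
#' @param threshold Band half-width in ppm (default 0.1).
#' @return A list of class `disorder_verdict`: `verdict`
#'   (`"random-coil"`/`"structured"`), `threshold`, `n_assigned`,
#'   `offending` (tibble).
#' @export
classify_disorder <- function(deltas, threshold = 0.1) {
  if (nrow(deltas) == 0) abort("no assigned residues; disorder is indeterminate")
  offending <- deltas[abs(deltas$delta_delta) > threshold, , drop = FALSE]
  structure(
    list(
      verdict = if (nrow(offending) == 0) "random-coil" else "structured",
      threshold = threshold, n_assigned = nrow(deltas),
      offending = as_tibble(offending)
    ),
    class = "disorder_verdict"
  )
}

#' @export
print.disorder_verdict <- function(x, ...) {
  cat(sprintf("Halpha conformational-shift verdict: %s (%d residues, |dd| <= %.2g ppm)\n",
              x$verdict, x$n_assigned, x$threshold))
  if (nrow(x$offending)) {
    cat("offending residues:",
        paste0(x$offending$residue, x$offending$position, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize NOE connectivity classes
#'
#' Counts sequential (j - i = 1), medium-range (2 <= j - i <= 4) and
#' long-range (j - i > 4) contacts. A contact set is coil-consistent when
#' only sequential NOEs are present (and at least one is); an empty set is
#' indeterminate.
#'
#' @param contacts A data frame with columns `i`, `j` (residue positions,
#'   i <= j) and optionally `class` (e.g. "aN", "bN", "ad"), `intensity`
#'   ("strong"/"medium"/"weak"), `ambiguous` (logical).
#' @return A tibble with `sequential`, `medium`, `long`, `intraresidue`
#'   counts and `verdict`.
#' @export
noe_connectivity_summary <- function(contacts) {
  if (nrow(contacts) == 0) {
    return(tibble(sequential = 0L, medium = 0L, long = 0L, intraresidue = 0L,
                  verdict = "indeterminate"))
  }
  if (any(contacts$i > contacts$j)) abort("contacts must have i <= j")
  if ("intensity" %in% names(contacts) &&
      !all(contacts$intensity %in% c("strong", "medium", "weak"))) {
    abort("intensity classes must be strong/medium/weak")
  }
  sep <- contacts$j - contacts$i
  sequential <- sum(sep == 1L)
  medium <- sum(sep >= 2L & sep <= 4L)
  long <- sum(sep > 4L)
  verdict <- if (medium == 0L && long == 0L && sequential >= 1L) {
    "coil-consistent"
  } else if (medium > 0L || long > 0L) {
    "not-coil-consistent"
  } else {
    "indeterminate"
  }
  tibble(sequential = sequential, medium = medium, long = long,
         intraresidue = sum(sep == 0L), verdict = verdict)
}
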