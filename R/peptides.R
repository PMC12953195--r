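#' Average residue mass model for capped peptides
#'
#' Standard average (not monoisotopic) masses of the 20 canonical amino-acid
#' residues, the mass of one water molecule added per chain, and the mass
#' deltas of the two common synthetic terminal caps: N-terminal acetylation
#' (+42.04 Da) and C-terminal amidation (-0.98 Da). Cysteine contributes its
#' reduced (free thiol) mass; no cystine correction is applied.
#'
#' @param residue_masses Named numeric vector of residue masses (Da), one per
#'   one-letter code. Defaults to the standard average-mass table.
#' @param water_mass Mass of water added per peptide chain (Da).
#' @param acetyl_delta Mass added by an N-terminal acetyl cap (Da).
#' @param amide_delta Mass added by a C-terminal amide cap (Da).
#' @return A list of class `mass_model`.
#' @export
#' @examples
#' average_mass("G") # free glycine, 75.07 Da
mass_model <- function(residue_masses = NULL,
                       water_mass = 18.0153,
                       acetyl_delta = 42.0367,
                       amide_delta = -0.9847) {
  if (is.null(residue_masses)) {
    residue_masses <- c(
      G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
      T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
      D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
      H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
    )
  }
  stopifnot(all(residue_masses > 0), water_mass > 0, acetyl_delta > 0)
  structure(
    list(residue_masses = residue_masses, water_mass = water_mass,
         acetyl_delta = acetyl_delta, amide_delta = amide_delta),
    class = "mass_model"
  )
}

#' Per-residue molar absorptivity model
#'
#' Additive per-residue molar extinction coefficients at stated wavelengths.
#' The 280 nm entries are the standard Trp/Tyr values (5500 and
#' 1490 M-1 cm-1); the per-phenylalanine coefficient at 258 nm is a
#' configurable default of 200 M-1 cm-1 for peptides lacking Trp/Tyr.
#'
#' @param coefficients A tibble with columns `residue`, `wavelength` (nm) and
#'   `epsilon` (M-1 cm-1). Residues with no entry contribute zero.
#' @return A tibble of class `extinction_model`.
#' @export
extinction_model <- function(coefficients = NULL) {
  if (is.null(coefficients)) {
    coefficients <- tibble(
      residue = c("W", "Y", "F"),
      wavelength = c(280, 280, 258),
      epsilon = c(5500, 1490, 200)
    )
  }
  stopifnot(all(coefficients$epsilon >= 0))
  structure(as_tibble(coefficients), class = c("extinction_model", class(tibble())))
}

.check_sequence <- function(sequence) {
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]*$", sequence)
  if (!all(ok)) {
    bad <- sequence[!ok][1]
    pos <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", bad)
    abort(sprintf(
      "sequence contains a non-canonical residue '%s' at position %d",
      substr(bad, pos, pos), pos
    ))
  }
  invisible(sequence)
}

#' Parse annotated peptide sequences with intact-protein numbering
#'
#' Parses entries of the form
#' `"H^361^KTLPVVFDSPRNGELQDFPYKRIL^385^ (PADI3-NLS1)"`: a one-letter
#' sequence in which the first residue carries the start index of the span in
#' the numbering of the intact parent protein and a later residue carries the
#' end index. Residues after the end-indexed residue (e.g., a tyrosine added
#' for quantification) are recorded as extra residues outside the numbered
#' span. Both caret-superscript (`K^520^`) and plain-digit (`K520`)
#' annotations are accepted; whitespace is ignored. A trailing parenthetical
#' becomes the peptide name.
#'
#' @param text Character vector of annotated sequence strings.
#' @param n_cap,c_cap Terminal caps, `"acetyl"`/`"free"` and
#'   `"amide"`/`"free"`. Recycled along `text`.
#' @param predictor_score Optional numeric vector of externally computed NLS
#'   predictor scores; carried through, never computed here.
#' @return A tibble with one row per peptide: `name`, `sequence` (numbered
#'   span plus extras), `start_residue`, `end_residue`, `n_cap`, `c_cap`,
#'   `extra_residues` (list column of tibbles with `position_tag`,
#'   `residue`), `predictor_score`.
#' @export
#' @examples
#' parse_annotated_sequence("H^361^KTLPVVFDSPRNGELQDFPYKRIL^385^ (PADI3-NLS1)")
parse_annotated_sequence <- function(text, n_cap = "acetyl", c_cap = "amide",
                                     predictor_score = NA_real_) {
  n_cap <- rep(match.arg(n_cap, c("acetyl", "free"), several.ok = FALSE), length(text))
  c_cap <- rep(match.arg(c_cap, c("amide", "free"), several.ok = FALSE), length(text))
  predictor_score <- rep_len(predictor_score, length(text))
  out <- Map(
    function(x, nc, cc, score) {
      raw <- x
      name <- NA_character_
      m <- regmatches(x, regexec("\\(([^()]+)\\)\\s*$", x))[[1]]
      if (length(m) == 2) {
        name <- m[2]
        x <- sub("\\([^()]+\\)\\s*$", "", x)
      }
      x <- gsub("\\s+", "", x)
      # tokens: residue letter optionally followed by a (caret-)superscript index
      tokens <- gregexpr("[A-Za-z](\\^?[0-9]+\\^?)?", x)[[1]]
      pieces <- regmatches(x, gregexpr("[A-Za-z](\\^?[0-9]+\\^?)?", x))[[1]]
      if (sum(attr(tokens, "match.length")) != nchar(x)) {
        off <- setdiff(seq_len(nchar(x)),
                       unlist(mapply(function(s, l) seq(s, s + l - 1), tokens,
                                     attr(tokens, "match.length"), SIMPLIFY = FALSE)))
        abort(sprintf("malformed sequence annotation near '%s' in \"%s\"",
                      substr(x, min(off), min(off)), raw))
      }
      res <- toupper(substr(pieces, 1, 1))
      num <- suppressWarnings(as.integer(gsub("[^0-9]", "", pieces)))
      numbered <- which(!is.na(num))
      if (length(numbered) == 0) {
        start <- 1L
        end <- length(res)
        extras_idx <- integer(0)
      } else if (length(numbered) > 2) {
        abort(sprintf("more than two numbered residues in \"%s\"", raw))
      } else {
        if (numbered[1] != 1L) {
          abort(sprintf("first residue must carry the start index in \"%s\"", raw))
        }
        start <- num[numbered[1]]
        end_tok <- numbered[length(numbered)]
        end <- num[end_tok]
        span_len <- end_tok # residues 1..end_tok are the numbered span
        if (end - start + 1L != span_len) {
          abort(sprintf(
            "span %d-%d implies %d residues but %d are annotated in \"%s\"",
            start, end, end - start + 1L, span_len, raw
          ))
        }
        extras_idx <- if (end_tok < length(res)) seq(end_tok + 1L, length(res)) else integer(0)
      }
      extras <- tibble(
        position_tag = if (length(extras_idx)) paste0("C+", seq_along(extras_idx)) else character(0),
        residue = res[extras_idx]
      )
      seq_str <- paste(res, collapse = "")
      .check_sequence(seq_str)
      tibble(
        name = name, sequence = seq_str,
        start_residue = as.integer(start), end_residue = as.integer(end),
        n_cap = nc, c_cap = cc,
        extra_residues = list(extras),
        predictor_score = score
      )
    },
    text, n_cap, c_cap, predictor_score
  )
  dplyr::bind_rows(out)
}

#' Average molecular mass of a capped peptide
#'
#' Sum of average residue masses plus one water, plus the terminal cap
#' deltas. Deterministic; matches synthesis certificates to ~0.1 Da.
#'
#' @param sequence Character vector of one-letter sequences, or a peptide
#'   tibble from [parse_annotated_sequence()] (whose `sequence`, `n_cap`,
#'   `c_cap` columns are then used).
#' @param n_cap,c_cap Terminal caps (ignored when `sequence` is a tibble).
#' @param model A [mass_model()].
#' @return Numeric vector of masses in Da.
#' @export
#' @examples
#' average_mass("HKTLPVVFDSPRNGELQDFPYKRIL") # ~3011.5 Da capped
average_mass <- function(sequence, n_cap = "acetyl", c_cap = "amide",
                         model = mass_model()) {
  if (is.data.frame(sequence)) {
    df <- sequence
    return(purrr::pmap_dbl(
      list(df$sequence, df$n_cap, df$c_cap),
      function(s, nc, cc) average_mass(s, nc, cc, model)
    ))
  }
  n_cap <- match.arg(n_cap, c("acetyl", "free"))
  c_cap <- match.arg(c_cap, c("amide", "free"))
  .check_sequence(sequence)
  cap_delta <- (if (n_cap == "acetyl") model$acetyl_delta else 0) +
    (if (c_cap == "amide") model$amide_delta else 0)
  vapply(sequence, function(s) {
    res <- strsplit(s, "")[[1]]
    unknown <- which(!res %in% names(model$residue_masses))
    if (length(unknown)) {
      abort(sprintf("unknown residue '%s' at position %d", res[unknown[1]], unknown[1]))
    }
    sum(model$residue_masses[res]) + model$water_mass + cap_delta
  }, numeric(1), USE.NAMES = FALSE)
}

#' Molar extinction coefficient of a peptide at a wavelength
#'
#' Linear sum of per-residue coefficients from an [extinction_model()]. A
#' zero result is legal (e.g., a peptide with no Trp/Tyr at 280 nm) but is
#' flagged with a warning suggesting phenylalanine-based quantification at
#' 258 nm, since such a peptide cannot be quantified at 280 nm.
#'
#' @param sequence One-letter sequence string (or vector).
#' @param wavelength Wavelength in nm.
#' @param model An [extinction_model()].
#' @param warn_zero Warn when the coefficient is zero.
#' @return Numeric vector, M-1 cm-1.
#' @export
extinction_coefficient <- function(sequence, wavelength = 280,
                                   model = extinction_model(), warn_zero = TRUE) {
  .check_sequence(sequence)
  entries <- model[model$wavelength == wavelength, , drop = FALSE]
  eps <- setNames(entries$epsilon, entries$residue)
  out <- vapply(sequence, function(s) {
    res <- strsplit(s, "")[[1]]
    sum(eps[res], na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  if (warn_zero && any(out == 0)) {
    warn(paste0(
      "extinction coefficient is zero at ", wavelength,
      " nm; quantify via phenylalanine absorbance at 258 nm instead"
    ))
  }
  out
}

#' Concentration from UV absorbance (Beer-Lambert)
#'
#' @param absorbance Absorbance (AU), blank-subtracted.
#' @param epsilon Molar extinction coefficient (M-1 cm-1), > 0.
#' @param path Cuvette path length (cm).
#' @return Concentration in M.
#' @export
concentration_from_absorbance <- function(absorbance, epsilon, path = 1) {
  if (any(epsilon <= 0)) {
    abort(paste(
      "epsilon must be positive; for peptides with no Trp/Tyr use the",
      "phenylalanine coefficient at 258 nm (extinction_model())"
    ))
  }
  stopifnot(all(path > 0), all(absorbance >= 0))
  absorbance / (epsilon * path)
}

#' Aromatic residue inventory with intact-protein numbering
#'
#' Positions of His, Phe, Tyr and Trp in each peptide, reported in the
#' numbering of the intact parent protein. Extra residues outside the
#' numbered span are reported with their position tags.
#'
#' @param peptides A peptide tibble from [parse_annotated_sequence()].
#' @return A tibble with `name`, `residue`, `position` (integer, NA for extra
#'   residues), `position_tag` (character).
#' @export
aromatic_inventory <- function(peptides) {
  purrr::pmap(
    list(peptides$name, peptides$sequence, peptides$start_residue,
         peptides$end_residue, peptides$extra_residues),
    function(name, seq, start, end, extras) {
      res <- strsplit(seq, "")[[1]]
      span_len <- end - start + 1L
      span <- utils::head(res, span_len)
      pos <- start + seq_along(span) - 1L
      keep <- span %in% c("H", "F", "Y", "W")
      main <- tibble(
        name = name, residue = span[keep], position = pos[keep],
        position_tag = as.character(pos[keep])
      )
      ex <- extras[extras$residue %in% c("H", "F", "Y", "W"), , drop = FALSE]
      extra <- tibble(
        name = name, residue = ex$residue, position = NA_integer_,
        position_tag = ex$position_tag
      )
      dplyr::bind_rows(main, extra)
    }
  ) |> dplyr::bind_rows()
}

#' Physicochemical property table for a set of peptides
#'
#' Data-frame-first convenience wrapper: adds capped average mass, extinction
#' coefficients at 280 and 258 nm, and aromatic counts to a peptide tibble.
#'
#' @param peptides A peptide tibble from [parse_annotated_sequence()].
#' @param mass A [mass_model()].
#' @param extinction An [extinction_model()].
#' @return The input tibble with columns `mass_da`, `epsilon_280`,
#'   `epsilon_258`, `n_trp`, `n_tyr`, `n_phe`, `n_his` appended.
#' @export
peptide_properties <- function(peptides, mass = mass_model(),
                               extinction = extinction_model()) {
  count_res <- function(seq, r) {
    vapply(strsplit(seq, ""), function(x) sum(x == r), integer(1))
  }
  peptides |>
    dplyr::mutate(
      mass_da = average_mass(peptides, model = mass),
      epsilon_280 = extinction_coefficient(.data$sequence, 280, extinction,
                                           warn_zero = FALSE),
      epsilon_258 = extinction_coefficient(.data$sequence, 258, extinction,
                                           warn_zero = FALSE),
      n_trp = count_res(.data$sequence, "W"),
      n_tyr = count_res(.data$sequence, "Y"),
      n_phe = count_res(.data$sequence, "F"),
      n_his = count_res(.data$sequence, "H")
    )
}

#' Read plain FASTA sequences as a peptide tibble
#'
#' Minimal FASTA-to-tibble reader for peptide input when no position
#' annotation is available; numbering then starts at 1 and caps are supplied
#' by the caller.
#'
#' @param path Path to a FASTA file.
#' @inheritParams parse_annotated_sequence
#' @return A peptide tibble as from [parse_annotated_sequence()].
#' @export
read_peptides_fasta <- function(path, n_cap = "acetyl", c_cap = "amide") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  idx <- grepl("^>", lines)
  if (!any(idx) || !idx[1]) abort("not a FASTA file: no leading '>' header")
  grp <- cumsum(idx)
  headers <- sub("^>\\s*", "", lines[idx])
  seqs <- vapply(split(lines[!idx], grp[!idx]), paste, character(1), collapse = "")
  seqs <- toupper(gsub("\\s", "", seqs))
  .check_sequence(seqs)
  tibble(
    name = headers, sequence = unname(seqs),
    start_residue = 1L, end_residue = unname(nchar(seqs)),
    n_cap = match.arg(n_cap, c("acetyl", "free")),
    c_cap = match.arg(c_cap, c("amide", "free")),
    extra_residues = list(tibble(position_tag = character(0), residue = character(0))),
    predictor_score = NA_real_
  )
}
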