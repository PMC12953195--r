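test_that("annotated sequences parse with span, extras and name", {
  p <- parse_annotated_sequence("H^361^KTLPVVFDSPRNGELQDFPYKRIL^385^ (PADI3-NLS1)")
  expect_equal(p$name, "PADI3-NLS1")
  expect_equal(nchar(p$sequence), 25)
  expect_equal(p$start_residue, 361L)
  expect_equal(p$end_residue, 385L)
  expect_equal(nrow(p$extra_residues[[1]]), 0)

  # single residue, start = end
  p1 <- parse_annotated_sequence("A^1^")
  expect_equal(p1$sequence, "A")
  expect_equal(p1$start_residue, 1L)
  expect_equal(p1$end_residue, 1L)

  # extra C-terminal residue outside the numbered span
  p2 <- parse_annotated_sequence("K^499^LFREKQKDGHGEAIMFKGLGGMSSKRIT^527^Y")
  expect_equal(p2$end_residue - p2$start_residue + 1L, 29L)
  expect_equal(nchar(p2$sequence), 30)
  expect_equal(p2$extra_residues[[1]]$residue, "Y")

  # plain-digit annotation and whitespace tolerance
  p3 <- parse_annotated_sequence("H361 KTLPVVFDSPRNGELQDFPYKRIL385")
  expect_equal(p3$sequence, p$sequence)
  expect_equal(p3$start_residue, 361L)
})

test_that("malformed annotations fail with informative errors", {
  expect_error(parse_annotated_sequence("H^361^KTL^999^PVV^385^"),
               "more than two numbered")
  # span 361-385 is 25 residues but only 10 are given
  expect_error(parse_annotated_sequence("H^361^KTLPVVFD^385^"), "span")
  expect_error(parse_annotated_sequence("A^1^XG^3^"), "non-canonical")
})

test_that("capped average masses match synthesis-certificate values", {
  presets <- padi_peptide_presets()
  peps <- parse_annotated_sequence(presets$entry)
  masses <- average_mass(peps)
  # PADI3-NLS1 and PADI2-NLS2 (with its added Tyr) agree within 0.2 Da
  expect_lt(abs(masses[presets$name == "PADI3-NLS1"] - 3011.42), 0.2)
  expect_lt(abs(masses[presets$name == "PADI2-NLS2"] - 3455.00), 0.2)
  expect_lt(abs(masses[presets$name == "PADI3-NLS2"] - 3539.08), 0.2)
  # free glycine is just residue + water
  expect_lt(abs(average_mass("G", "free", "free") - 75.07), 0.01)
})

test_that("the printed PADI1-NLS1 mass matches the Cys, not the Ser, variant", {
  ser <- average_mass("KHQAKRSINEMLADRHLQRDNLHAQKSIDW")
  cys <- average_mass("KHQAKRSINEMLADRHLQRDNLHAQKCIDW")
  expect_lt(abs(cys - 3697.16), 0.2)
  expect_gt(abs(ser - 3697.16), 10) # the published table reflects the wild type
})

test_that("mass is additive over concatenation and caps shift it by fixed deltas", {
  set.seed(11)
  aas <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")
  for (k in 1:5) {
    s1 <- paste(sample(aas, 8, TRUE), collapse = "")
    s2 <- paste(sample(aas, 12, TRUE), collapse = "")
    m12 <- average_mass(paste0(s1, s2), "free", "free")
    m1 <- average_mass(s1, "free", "free")
    m2 <- average_mass(s2, "free", "free")
    expect_equal(m12, m1 + m2 - 18.0153, tolerance = 1e-9)
    free <- average_mass(s1, "free", "free")
    expect_equal(average_mass(s1, "acetyl", "free") - free, 42.0367, tolerance = 0.01)
    expect_equal(average_mass(s1, "free", "amide") - free, -0.9847, tolerance = 0.01)
  }
})

test_that("extinction coefficients sum linearly over residues", {
  # importin-like composition: six Trp and six Tyr
  expect_equal(
    extinction_coefficient("WWWWWWYYYYYY", 280),
    6 * 5500 + 6 * 1490
  )
  expect_equal(extinction_coefficient("W", 280), 5500)
  # a peptide with no Trp/Tyr is flagged toward Phe-based quantification
  expect_warning(
    e <- extinction_coefficient("REVLKRELGLAESDIIDIPQLFKTERKKAT", 280),
    "258"
  )
  expect_equal(e, 0)
  # additivity over concatenation at any wavelength
  expect_equal(
    extinction_coefficient("WYF", 258, warn_zero = FALSE),
    extinction_coefficient("WY", 258, warn_zero = FALSE) +
      extinction_coefficient("F", 258, warn_zero = FALSE)
  )
})

test_that("Beer-Lambert concentration behaves and guards its inputs", {
  expect_equal(concentration_from_absorbance(0, 41940), 0)
  expect_equal(concentration_from_absorbance(0.4194, 41940, 1), 1e-5)
  expect_equal(
    concentration_from_absorbance(0.4, 41940, 2),
    concentration_from_absorbance(0.4, 41940, 1) / 2
  )
  expect_error(concentration_from_absorbance(0.1, 0), "258")
})

test_that("aromatic inventory reports intact-protein positions", {
  presets <- padi_peptide_presets()
  peps <- parse_annotated_sequence(presets$entry)
  inv <- aromatic_inventory(peps)
  p3 <- inv[inv$name == "PADI3-NLS1", ]
  expect_setequal(p3$position[p3$residue == "F"], c(368, 379))
  expect_equal(p3$position[p3$residue == "H"], 361)
  expect_equal(p3$position[p3$residue == "Y"], 381)
  expect_false("W" %in% p3$residue)
  p1 <- inv[inv$name == "PADI1-NLS1", ]
  expect_equal(p1$position[p1$residue == "W"], 549)
  # the added PADI2-NLS2 tyrosine is outside the numbered span
  p2 <- inv[inv$name == "PADI2-NLS2", ]
  expect_true(any(p2$residue == "Y" & is.na(p2$position)))
})

test_that("FASTA input round-trips into the peptide table", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">pep1", "HKTLPVVFDS", "PRNGELQDFPYKRIL", ">pep2", "AW"), tf)
  peps <- read_peptides_fasta(tf)
  expect_equal(peps$sequence[1], "HKTLPVVFDSPRNGELQDFPYKRIL")
  expect_equal(peps$name, c("pep1", "pep2"))
  expect_equal(peps$end_residue, c(25L, 2L))
})
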