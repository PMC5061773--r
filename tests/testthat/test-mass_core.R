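test_that("peptide_mh agrees with the atomic-composition oracle", {
  # frozen single-residue example: Gly 57.02146 + water 18.01056 + proton
  expect_equal(round(peptide_mh("G"), 3), 76.039)
  set.seed(11)
  for (len in c(1, 5, 12, 40)) {
    pep <- random_peptide(len)
    expect_equal(peptide_mh(pep), oracle_mh(pep), tolerance = 1e-6)
  }
  pep <- paste0(random_peptide(10), "M")
  expect_equal(peptide_mh(pep, terminal_met = TRUE),
               oracle_mh(pep, terminal_met = TRUE), tolerance = 1e-6)
})

test_that("peptide_mh validates its input", {
  expect_error(peptide_mh(""), "non-empty")
  expect_error(peptide_mh("ACGX"), "position 4")
  expect_error(peptide_mh("ACDE", terminal_met = TRUE), "end in M")
})

test_that("mass additivity holds for concatenation", {
  w <- mass_table()$water; p <- mass_table()$proton
  set.seed(7)
  for (i in 1:5) {
    a <- random_peptide(sample(3:20, 1)); b <- random_peptide(sample(3:20, 1))
    expect_equal(peptide_mh(paste0(a, b)),
                 peptide_mh(a) + peptide_mh(b) - w - p, tolerance = 1e-9)
  }
})

test_that("terminal-Met convention resolves to homoserine lactone on the table", {
  catalog <- pd_catalog()
  res <- suppressMessages(resolve_met_convention(
    data.frame(sequence = catalog$protein_seq,
               terminal_met = catalog$terminal_met,
               printed_mh = catalog$printed_mh)))
  expect_identical(res$convention, "homoserine_lactone")
  expect_equal(res$delta, -48.003371)
  expect_equal(nrow(res$residuals), 11)  # 11 terminal-Met records
})

test_that("resolve_met_convention surfaces inconsistencies instead of guessing", {
  expect_error(resolve_met_convention(
    data.frame(sequence = "ACDE", terminal_met = FALSE, printed_mh = 500)),
    "nothing to resolve")
  corrupt <- data.frame(sequence = c("ACDM", "EFGM"), terminal_met = TRUE,
                        printed_mh = c(peptide_mh("ACDM", TRUE), 9999))
  expect_error(resolve_met_convention(corrupt), "residual")
})

test_that("CNBr digestion cuts after Met and flags converted fragments", {
  d <- digest("ACDMEFG", "cnbr")
  expect_identical(d$sequence, c("ACDM", "EFG"))
  expect_identical(d$terminal_met, c(TRUE, FALSE))
  expect_identical(digest("ACDEFG", "cnbr")$sequence, "ACDEFG")
  # protein-terminal Met is converted too
  d2 <- digest("ACDM", "cnbr")
  expect_true(d2$terminal_met)
})

test_that("trypsin respects Pro blocking and modified-Lys blocking", {
  # K before P is not cleaved
  expect_identical(digest("AAKPGGKAA", "trypsin")$sequence, c("AAKPGGK", "AA"))
  # acetylated Lys-40 of the packaged N-terminal fragment blocks cleavage,
  # merging the fragments flanking Lys-40 (the long/short peptide pair logic)
  nterm <- load_catalog(system.file("extdata", "tua_nterm_synthetic.fasta",
                                    package = "tubulinptm"))$protein_seq
  free <- digest(nterm, "trypsin")
  blocked <- digest(nterm, "trypsin", modified_positions = 40L)
  expect_true(40L %in% free$end)
  expect_false(40L %in% blocked$end)
  expect_equal(nrow(blocked), nrow(free) - 1L)
  # the peptide C-terminal to an exposed Lys-40 starts at residue 41
  expect_true(41L %in% free$start)
})

test_that("digestion conserves sequence and mass", {
  w <- mass_table()$water; p <- mass_table()$proton
  set.seed(13)
  for (protease in c("cnbr", "trypsin")) {
    for (i in 1:5) {
      prot <- random_peptide(60)
      d <- digest(prot, protease)
      expect_identical(paste(d$sequence, collapse = ""), prot)
      # neutral fragment masses sum to protein neutral mass + (n-1) waters
      frag_neutral <- sum(peptide_mh(d$sequence) - p)
      expect_equal(frag_neutral, peptide_mh(prot) - p + (nrow(d) - 1) * w,
                   tolerance = 1e-9)
    }
  }
})
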