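test_that("extract_region does the stated index arithmetic", {
  set.seed(5)
  tr <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
  r <- extract_region(tr, stop_pos = 840, cds_tail_bp = 120, utr_bp = 80)
  expect_equal(r$start, 721)
  expect_equal(r$end, 900)
  expect_equal(r$length_bp, 180)
  expect_identical(r$sequence, substr(tr, 721, 900))
  # transcript shorter than the requested tail: take what exists, warn
  short <- substr(tr, 1, 150)
  expect_warning(r2 <- extract_region(short, stop_pos = 150,
                                      cds_tail_bp = 200, utr_bp = 0),
                 "truncated")
  expect_equal(r2$length_bp, 150)
  expect_error(extract_region(tr, 840, 0, 0), "empty region")
})

test_that("reads map by the stated filters and best-hit rule", {
  regs <- make_paralog_regions()
  # exact 75-mer from the unique part of regA
  read <- substr(regs[["regA"]], 110, 184)
  a <- map_read(read, regs)
  expect_equal(a$status, "assigned")
  expect_equal(a$region_id, "regA")
  expect_equal(a$mismatches, 0)
  expect_equal(a$coverage_fraction, 1)

  # 2 mismatches over 75 bp exceed the 2% allowance (floor(1.5) = 1)
  bad <- read
  substr(bad, 10, 10) <- if (substr(bad, 10, 10) == "A") "C" else "A"
  substr(bad, 50, 50) <- if (substr(bad, 50, 50) == "G") "T" else "G"
  b <- map_read(bad, regs)
  expect_equal(b$status, "filtered_mismatch")
  # a single mismatch is allowed
  one <- read
  substr(one, 10, 10) <- if (substr(one, 10, 10) == "A") "C" else "A"
  expect_equal(map_read(one, regs)$status, "assigned")

  # a read from the shared block matches both paralogs: discarded tie
  tie <- substr(regs[["regA"]], 60, 134)
  expect_equal(map_read(tie, regs)$status, "ambiguous_tie")

  # reverse-complement reads map on the minus strand unless stranded
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  m <- map_read(rc, regs)
  expect_equal(m$status, "assigned")
  expect_equal(m$strand, "-")
  expect_false(map_read(rc, regs, stranded = TRUE)$status == "assigned")

  # unrelated sequence is unmapped
  set.seed(99)
  rand <- paste(sample(c("A", "C", "G", "T"), 75, TRUE), collapse = "")
  expect_equal(map_read(rand, regs)$status, "unmapped")
})

test_that("statuses partition the read set and filters are monotone", {
  regs <- make_paralog_regions()
  rd <- simulate_reads(regs, c(regA = 0.6, regB = 0.4), n_reads = 400,
                       error_rate = 0.02, seed = 31)
  aln <- map_reads(rd$reads, regs)
  expect_equal(nrow(aln), 400)
  expect_true(all(aln$status %in% c("assigned", "filtered_coverage",
                                    "filtered_mismatch", "ambiguous_tie",
                                    "unmapped")))
  n_assigned <- sum(aln$status == "assigned")
  # stricter coverage or mismatch settings never assign more reads
  stricter_cov <- map_reads(rd$reads, regs, min_coverage = 0.99)
  stricter_mm <- map_reads(rd$reads, regs, max_mismatch_frac = 0.01)
  expect_lte(sum(stricter_cov$status == "assigned"), n_assigned)
  expect_lte(sum(stricter_mm$status == "assigned"), n_assigned)
})

test_that("FPKM follows its defining formula", {
  region <- setNames(paste(rep("ACGT", 50), collapse = ""), "TUB15")  # 200 bp
  aln <- data.frame(region_id = rep("TUB15", 100),
                    status = rep("assigned", 100))
  expect_equal(compute_fpkm(aln, region, 1e6)$fpkm, 500)
  # doubling the library halves FPKM
  expect_equal(compute_fpkm(aln, region, 2e6)$fpkm, 250)
  # zero-count regions are reported with FPKM 0
  none <- data.frame(region_id = character(), status = character())
  expect_equal(compute_fpkm(none, region, 1e6)$fpkm, 0)
  expect_error(compute_fpkm(aln, region, 0), "positive")
})

test_that("concordance report correlates and flags the TUB18 pattern", {
  ids <- paste0("TUB", 11:18)
  fpkm <- data.frame(isotype_id = ids,
                     fpkm = c(300, 350, 400, 450, 500, 550, 600, 650))
  prot_prop <- data.frame(isotype_id = ids, family = "TUB",
                          relative_abundance = fpkm$fpkm / sum(fpkm$fpkm))
  rep1 <- concordance_report(prot_prop, fpkm)
  expect_equal(rep1$by_family$spearman, 1.0)
  expect_false(any(rep1$per_isotype$flagged))
  # suppress the most transcribed isotype 10x below proportionality
  supp <- prot_prop
  supp$relative_abundance[supp$isotype_id == "TUB18"] <-
    supp$relative_abundance[supp$isotype_id == "TUB18"] / 10
  rep2 <- concordance_report(supp, fpkm)
  expect_true(rep2$per_isotype$flagged[rep2$per_isotype$isotype_id == "TUB18"])
  expect_false(any(rep2$per_isotype$flagged[rep2$per_isotype$isotype_id != "TUB18"]))
  # fewer than 3 shared isotypes: correlation omitted with a warning
  expect_warning(r3 <- concordance_report(prot_prop[1:2, ], fpkm[1:2, ]),
                 "fewer than 3")
  expect_true(is.na(r3$by_family$spearman))
})
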