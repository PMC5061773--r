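catalog <- pd_catalog()
rp <- suppressMessages(reporter_peptides(catalog))

test_that("manifests validate their ground-truth knobs", {
  expect_error(simulation_manifest(1, c(TUA1 = 0.5, TUA2 = 0.4)),
               "sum to 1")
  expect_error(simulation_manifest(1, c(0.5, 0.5)), "names")
  m <- simulation_manifest(7, c(TUA1 = 0.6, TUA5 = 0.4))
  expect_s3_class(m, "simulation_manifest")
  expect_equal(m$read_params$read_length, 75)
  expect_equal(m$read_params$error_rate, 0.005)
  # hash is stable and sensitive
  expect_identical(manifest_hash(m), manifest_hash(m))
  m2 <- simulation_manifest(8, c(TUA1 = 0.6, TUA5 = 0.4))
  expect_false(identical(manifest_hash(m), manifest_hash(m2)))
})

test_that("transcript families concentrate divergence in the tail", {
  fam <- make_transcript_family(catalog, seed = 41)
  expect_equal(nrow(fam), 28)
  # cores are identical across paralogs by construction
  cores <- substr(fam$transcript, 1, fam$tail_start - 1)
  expect_equal(length(unique(cores)), 1)
  # zero divergence is the identity
  m0 <- simulate_family(fam, 0, seed = 42)
  expect_identical(m0$family$transcript, fam$transcript)
  expect_equal(nrow(m0$truth), 0)
  # at 3% core rate, tail rate is 5x: check counts against binomial bounds
  m3 <- simulate_family(fam, 0.03, seed = 42)
  in_tail <- m3$truth$pos >= fam$tail_start[match(m3$truth$isotype_id,
                                                  fam$isotype_id)]
  n_core_sites <- sum(fam$tail_start - 1)
  n_tail_sites <- sum(nchar(fam$transcript) - fam$tail_start + 1)
  core_n <- sum(!in_tail); tail_n <- sum(in_tail)
  expect_lt(abs(core_n - 0.03 * n_core_sites),
            4 * sqrt(0.03 * n_core_sites))
  expect_lt(abs(tail_n - 0.15 * n_tail_sites),
            4 * sqrt(0.15 * n_tail_sites))
  # truth log replays the mutations
  i <- which(m3$truth$isotype_id == "TUA1")[1]
  pos <- m3$truth$pos[i]
  expect_identical(substr(m3$family$transcript[fam$isotype_id == "TUA1"],
                          pos, pos), m3$truth$alt[i])
  # determinism
  m3b <- simulate_family(fam, 0.03, seed = 42)
  expect_identical(m3b$family$transcript, m3$family$transcript)
})

test_that("read simulation matches its multinomial ground truth", {
  regs <- make_paralog_regions()
  # degenerate mixture, no errors: every read is a perfect substring
  rd <- simulate_reads(regs, c(regA = 1), n_reads = 50, error_rate = 0,
                       seed = 43)
  expect_true(all(vapply(rd$reads, function(r)
    grepl(r, regs[["regA"]], fixed = TRUE), logical(1))))
  # origin counts within 3 sigma of the multinomial expectation
  regs3 <- c(regs, regC = make_paralog_regions(7)[["regA"]])
  p <- c(regA = 0.5, regB = 0.3, regC = 0.2)
  rd2 <- simulate_reads(regs3, p, n_reads = 10000, seed = 44)
  counts <- table(rd2$truth$isotype_id)[names(p)]
  for (j in seq_along(p)) {
    sd <- sqrt(10000 * p[j] * (1 - p[j]))
    expect_lt(abs(counts[j] - 10000 * p[j]), 3 * sd)
  }
  # byte-identical under the same seed, FASTQ round trip included
  rd3 <- simulate_reads(regs3, p, n_reads = 100, seed = 45)
  rd4 <- simulate_reads(regs3, p, n_reads = 100, seed = 45)
  expect_identical(rd3$reads, rd4$reads)
  tf <- tempfile(fileext = ".fq")
  write_fastq(rd3$reads, tf)
  expect_identical(read_fastq(tf), rd3$reads)
})

test_that("spectrum simulation encodes its truth and is reproducible", {
  sx <- simulate_spectrum(rp, c(TUA1 = 1),
                          ptm_spikes = data.frame(isotype = "TUA1",
                                                  modification = "dEY",
                                                  stoichiometry = 0.2),
                          seed = 46)
  iso <- enumerate_isoforms(rp[rp$isotype_id == "TUA1", ],
                            standard_modifications(c("unmodified", "dY", "dEY")))
  v <- scan_spectrum(sx$peaks, iso)
  expect_equal(v$verdict[v$modification == "dEY"], "detected")
  expect_equal(v$verdict[v$modification == "dY"], "absent")
  # base:spike apex ratio is the 1/stoichiometry ground truth
  apex <- sx$truth$apex_intensity
  expect_equal(apex[sx$truth$kind == "reporter"] /
                 apex[sx$truth$kind == "ptm_spike"], 5)
  expect_identical(simulate_spectrum(rp, c(TUA1 = 1), seed = 47)$peaks,
                   simulate_spectrum(rp, c(TUA1 = 1), seed = 47)$peaks)
  # spiking an inapplicable modification is an error
  expect_error(simulate_spectrum(rp, c(TUA5 = 1),
                                 ptm_spikes = data.frame(isotype = "TUA5",
                                                         modification = "dY",
                                                         stoichiometry = 0.1),
                                 seed = 48),
               "does not apply")
  # noise peaks are spaced >= 1.5 Da so they can never form an envelope
  noise <- simulate_spectrum(rp, c(TUA1 = 0), seed = 49)$peaks
  expect_true(all(diff(noise$mz) >= 1.5))
})
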