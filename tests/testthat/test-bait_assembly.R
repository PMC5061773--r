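set.seed(61)
.tx300 <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")

test_that("recruitment is seed-gated, alignment-verified and monotone", {
  reads <- tiling_reads(.tx300)
  bait <- substr(.tx300, 76, 225)  # middle 50%
  got <- recruit(reads, bait)
  # every read overlapping the bait by >= k is recruited
  expect_true(all(names(reads)[vapply(seq_along(reads), function(i) {
    s <- 1 + (i - 1) * 7
    min(225, s + 74) - max(76, s) + 1 >= 21
  }, logical(1))] %in% got))
  # unrelated reads share no k-mers
  set.seed(62)
  rand <- setNames(vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 75, TRUE), collapse = ""),
    character(1)), paste0("r", 1:10))
  expect_length(recruit(rand, bait), 0)
  # a second bait never removes recruited reads
  got2 <- recruit(reads, c(bait, substr(.tx300, 1, 100)))
  expect_true(all(got %in% got2))
  # reverse-complement reads are recruited too
  rc <- setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads[10:12]))), names(reads)[10:12])
  expect_setequal(recruit(rc, bait), recruit(reads[10:12], bait))
  expect_gt(length(recruit(reads[10:12], bait)), 0)
  expect_error(recruit(reads, bait, k = 9), "k >= 11")
})

test_that("greedy assembly reconstructs a tiled transcript exactly", {
  reads <- tiling_reads(.tx300)
  contigs <- assemble(reads, min_overlap = 30)
  expect_identical(contigs[1], .tx300)
  # two non-overlapping reads stay separate
  two <- c(a = substr(.tx300, 1, 75), b = substr(.tx300, 150, 224))
  expect_length(assemble(two), 2)
  expect_length(assemble(character(0)), 0)
})

test_that("assembly tolerates sequencing errors at 10x coverage", {
  set.seed(63)
  n <- 40
  starts <- sample.int(226, n, replace = TRUE)
  reads <- substring(.tx300, starts, starts + 74)
  reads <- vapply(reads, function(r) {
    k <- rbinom(1, 75, 0.005)
    if (k > 0) r <- mutate_seq(r, k / 75, sample.int(1e6, 1)) else r
  }, character(1))
  names(reads) <- sprintf("e%02d", seq_len(n))
  contigs <- assemble(c(tiling_reads(.tx300, by = 25), reads), min_overlap = 30)
  # longest contig aligns to the truth at >= 99% identity (errors cannot
  # propagate through exact-overlap merges, but may shorten the contig)
  d <- utils::adist(contigs[1], .tx300, partial = TRUE)[1]
  expect_lt(d / nchar(contigs[1]), 0.01)
  expect_gte(nchar(contigs[1]), 150)  # still a substantial reconstruction
})

test_that("the bait loop recovers a transcript 3% diverged from its bait", {
  true_tx <- .tx300
  ref_bait <- mutate_seq(true_tx, 0.03, seed = 64)
  reads <- tiling_reads(true_tx, by = 5)
  out <- iterate_assembly(reads, initial_baits = ref_bait,
                          reference = c(gene1 = ref_bait))
  expect_lte(out$iterations, 10)
  expect_identical(out$contigs[["gene1"]], true_tx)
})

test_that("the loop fixed point is detected early on perfect data", {
  reads <- tiling_reads(.tx300, by = 5)
  out <- iterate_assembly(reads, initial_baits = .tx300,
                          reference = c(gene1 = .tx300))
  expect_lte(out$iterations, 3)
  expect_identical(out$contigs[["gene1"]], .tx300)
  # repeating the loop from the stable bait changes nothing (idempotence)
  out2 <- iterate_assembly(reads, initial_baits = out$contigs[["gene1"]],
                           reference = c(gene1 = .tx300))
  expect_identical(out2$contigs, out$contigs)
})

test_that("baits recruiting nothing give an empty stable result", {
  set.seed(65)
  rand <- setNames(vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 75, TRUE), collapse = ""),
    character(1)), paste0("n", 1:20))
  out <- iterate_assembly(rand, initial_baits = .tx300,
                          reference = c(gene1 = .tx300))
  expect_equal(out$iterations, 1)
  expect_true(is.na(out$contigs[["gene1"]]))
})
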