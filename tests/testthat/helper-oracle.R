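# Independent mass oracle: computes MH+ from atomic elemental compositions,
# not from the package's residue-mass table.

.atomic <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
             O = 15.9949146221, S = 31.97207069)
.proton_oracle <- 1.00727646688

# residue (minus water) elemental compositions
.residue_formula <- list(
  G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2), D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2), K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1), F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

.formula_mass <- function(f) sum(.atomic[names(f)] * f)

oracle_mh <- function(sequence, terminal_met = FALSE) {
  letters <- strsplit(sequence, "")[[1]]
  resid <- sum(vapply(letters, function(a)
    .formula_mass(.residue_formula[[a]]), numeric(1)))
  water <- .formula_mass(c(H = 2, O = 1))
  delta <- if (terminal_met) -.formula_mass(c(C = 1, H = 4, S = 1)) else 0
  resid + water + .proton_oracle + delta
}

# random peptide generator for property tests
random_peptide <- function(len) {
  paste(sample(names(.residue_formula), len, replace = TRUE), collapse = "")
}

# small two-region reference used across mapping tests: 200 bp each, sharing
# a 100 bp central block to create genuine paralog ambiguity
make_paralog_regions <- function(seed = 42) {
  set.seed(seed)
  b <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  shared <- b(100)
  c(regA = paste0(b(50), shared, b(50)),
    regB = paste0(b(50), shared, b(50)))
}

# deterministic tiling reads (error-free) covering a sequence end to end
tiling_reads <- function(seq, read_length = 75, by = 7) {
  n <- nchar(seq)
  starts <- unique(c(seq(1, n - read_length + 1, by = by), n - read_length + 1))
  reads <- substring(seq, starts, starts + read_length - 1)
  stats::setNames(reads, sprintf("tile%03d", seq_along(starts)))
}

mutate_seq <- function(seq, rate, seed) {
  set.seed(seed)
  s <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(s)) < rate)
  for (p in hit) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

tmp_tsv <- function() tempfile(fileext = ".tsv")
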