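# Seeded simulators: paralog transcript families, stranded short reads, and
# MALDI peak lists with known ground truth. These stand in for the deposited
# instrument and sequencing data; every output is reproducible from
# (manifest, seed).

# run code under a local RNG state derived from seed, restoring afterwards
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# deterministic per-stage substream so stages can be re-run in isolation
.stage_seed <- function(seed, stage) {
  offsets <- c(family = 101L, reads = 211L, spectrum = 307L, demo = 401L)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% 2147483647L
}

#' Simulation manifest
#'
#' Bundles every ground-truth knob of a simulated experiment: per-family
#' isotype proportions, optional PTM spike-ins, read parameters and spectrum
#' parameters. Proportions must sum to 1 within each family (or be all zero
#' for a noise-only spectrum).
#'
#' @param seed integer master seed; all stage streams derive from it.
#' @param isotype_proportions named numeric vector (isotype id -> fraction).
#' @param ptm_spikes optional data.frame with \code{isotype, modification,
#'   stoichiometry} (fraction of the base reporter intensity, in [0, 1]).
#' @param read_params list: \code{n_reads} (default 8000), \code{read_length}
#'   (75, the library read length), \code{error_rate} (0.005 substitutions
#'   per base).
#' @param spectrum_params list: \code{n_noise_peaks} (50),
#'   \code{noise_mz_range} (c(3000, 4400)), \code{intensity_scale} (100),
#'   \code{envelope_decay} (0.7), \code{noise_intensity_max} (1).
#' @return list of class \code{simulation_manifest}.
#' @export
simulation_manifest <- function(seed = 1, isotype_proportions,
                                ptm_spikes = NULL,
                                read_params = list(),
                                spectrum_params = list()) {
  stopifnot(is.numeric(isotype_proportions),
            !is.null(names(isotype_proportions)),
            all(isotype_proportions >= 0), all(isotype_proportions <= 1))
  fam <- substr(names(isotype_proportions), 1, 3)
  for (f in unique(fam)) {
    s <- sum(isotype_proportions[fam == f])
    if (s > 0 && abs(s - 1) > 1e-9)
      stop("proportions for family ", f, " must sum to 1 (got ", s, ")")
  }
  if (!is.null(ptm_spikes)) {
    stopifnot(all(c("isotype", "modification", "stoichiometry") %in%
                    names(ptm_spikes)),
              all(ptm_spikes$stoichiometry >= 0),
              all(ptm_spikes$stoichiometry <= 1))
  }
  rp <- utils::modifyList(list(n_reads = 8000L, read_length = 75L,
                               error_rate = 0.005), read_params)
  sp <- utils::modifyList(list(n_noise_peaks = 50L,
                               noise_mz_range = c(3000, 4400),
                               intensity_scale = 100,
                               envelope_decay = 0.7,
                               noise_intensity_max = 1), spectrum_params)
  out <- list(seed = as.integer(seed), isotype_proportions = isotype_proportions,
              ptm_spikes = ptm_spikes, read_params = rp, spectrum_params = sp)
  class(out) <- "simulation_manifest"
  out
}

#' Fingerprint of a manifest (recorded in simulator output headers)
#' @param manifest a \code{simulation_manifest}.
#' @return md5 string of the serialized manifest.
#' @export
manifest_hash <- function(manifest) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(manifest, tf, version = 2)
  unname(tools::md5sum(tf))
}

# fixed codon per amino acid for deterministic reverse translation
.CODON <- c(A = "GCT", R = "AGA", N = "AAC", D = "GAT", C = "TGT", Q = "CAA",
            E = "GAA", G = "GGT", H = "CAC", I = "ATT", L = "CTT", K = "AAG",
            M = "ATG", F = "TTC", P = "CCA", S = "TCT", T = "ACT", V = "GTT",
            W = "TGG", Y = "TAC")

.revtrans <- function(aa) {
  paste(.CODON[strsplit(aa, "")[[1]]], collapse = "")
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

#' Synthetic paralog transcript family
#'
#' Emulates the statistical structure of the tubulin families: a core that is
#' near-identical across paralogs and divergence concentrated in the
#' C-terminal coding tail and 3'-UTR. Each isotype's transcript is a shared
#' random core, the deterministic reverse translation of its own reporter
#' peptide (paralog tails differ exactly where the peptides differ), a stop
#' codon, and an isotype-specific random UTR.
#'
#' @param catalog an \code{isotype_catalog} (one species).
#' @param core_len length of the shared upstream core (bp).
#' @param utr_len length of the per-isotype 3'-UTR (bp).
#' @param seed integer seed.
#' @return data.frame with \code{isotype_id, transcript, stop_pos,
#'   tail_start} (first base of the hypervariable tail).
#' @export
make_transcript_family <- function(catalog, core_len = 330, utr_len = 90,
                                   seed = 1) {
  stopifnot(nrow(catalog) > 0)
  .with_seed(seed, {
    core <- .rand_dna(core_len)
    do.call(rbind, lapply(seq_len(nrow(catalog)), function(i) {
      tail_nt <- .revtrans(catalog$protein_seq[i])
      cds <- paste0(core, tail_nt, "TAA")
      utr <- .rand_dna(utr_len)
      data.frame(isotype_id = catalog$id[i],
                 transcript = paste0(cds, utr),
                 stop_pos = nchar(cds),
                 tail_start = core_len + 1L,
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Mutate a transcript family with tail-concentrated divergence
#'
#' Per-gene point substitutions at rate \code{divergence} in the conserved
#' core and 5x that rate in the hypervariable tail + UTR, emulating families
#' whose members are 88-98% identical except for the C-terminus. A truth log
#' records every substitution.
#'
#' @param family data.frame from \code{\link{make_transcript_family}}.
#' @param divergence core substitution rate in [0, 0.1].
#' @param seed integer seed.
#' @return list with \code{family} (mutated) and \code{truth}
#'   (isotype_id, pos, ref, alt).
#' @export
simulate_family <- function(family, divergence, seed = 1) {
  stopifnot(divergence >= 0, divergence <= 0.1)
  bases <- c("A", "C", "G", "T")
  .with_seed(.stage_seed(seed, "family"), {
    truth <- list()
    for (i in seq_len(nrow(family))) {
      s <- strsplit(family$transcript[i], "")[[1]]
      rate <- ifelse(seq_along(s) >= family$tail_start[i],
                     5 * divergence, divergence)
      hit <- which(stats::runif(length(s)) < pmin(rate, 1))
      for (p in hit) {
        alt <- sample(setdiff(bases, s[p]), 1)
        truth <- c(truth, list(data.frame(isotype_id = family$isotype_id[i],
                                          pos = p, ref = s[p], alt = alt)))
        s[p] <- alt
      }
      family$transcript[i] <- paste(s, collapse = "")
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(isotype_id = character(), pos = integer(),
                 ref = character(), alt = character())
    list(family = family, truth = truth)
  })
}

#' Simulate stranded short reads from a region mixture
#'
#' Read origins are multinomial with the given proportions, start positions
#' uniform within each region, and substitution errors i.i.d. per base at
#' \code{error_rate}. Reads come from the forward strand (stranded library).
#'
#' @param regions named character vector of region/transcript sequences.
#' @param proportions named numeric vector over (a subset of) region names;
#'   normalized internally.
#' @param n_reads number of reads.
#' @param read_length read length (must not exceed the shortest region).
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return list with \code{reads} (named character) and \code{truth}
#'   (read_id, isotype_id, start, n_errors).
#' @export
simulate_reads <- function(regions, proportions, n_reads = 8000,
                           read_length = 75, error_rate = 0.005, seed = 1) {
  proportions <- proportions[proportions > 0]
  if (length(proportions) == 0L)
    return(list(reads = stats::setNames(character(0), character(0)),
                truth = data.frame(read_id = character(),
                                   isotype_id = character(),
                                   start = integer(), n_errors = integer())))
  stopifnot(all(names(proportions) %in% names(regions)),
            read_length <= min(nchar(regions[names(proportions)])))
  p <- proportions / sum(proportions)
  bases <- c("A", "C", "G", "T")
  .with_seed(.stage_seed(seed, "reads"), {
    origin <- sample(names(p), n_reads, replace = TRUE, prob = p)
    reads <- character(n_reads); starts <- integer(n_reads)
    nerr <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      src <- regions[[origin[i]]]
      starts[i] <- sample.int(nchar(src) - read_length + 1L, 1L)
      r <- substr(src, starts[i], starts[i] + read_length - 1L)
      k <- stats::rbinom(1L, read_length, error_rate)
      if (k > 0) {
        s <- strsplit(r, "")[[1]]
        pos <- sample.int(read_length, k)
        for (q in pos) s[q] <- sample(setdiff(bases, s[q]), 1)
        r <- paste(s, collapse = "")
      }
      reads[i] <- r; nerr[i] <- k
    }
    ids <- sprintf("read%06d", seq_len(n_reads))
    list(reads = stats::setNames(reads, ids),
         truth = data.frame(read_id = ids, isotype_id = origin,
                            start = starts, n_errors = nerr,
                            stringsAsFactors = FALSE))
  })
}

#' Write reads as FASTQ (Phred+33, constant quality)
#' @param reads named character vector.
#' @param path output path.
#' @param qual quality character applied to every base.
#' @export
write_fastq <- function(reads, path, qual = "I") {
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads), "+",
                           vapply(nchar(reads), function(n)
                             strrep(qual, n), character(1))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ path (Phred+33; qualities parsed but unused).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Simulate a MALDI peak list from an isotype mixture
#'
#' Each isotype with proportion > 0 contributes a 4-peak isotopic envelope at
#' its reporter MH+ (spacing 1.00235 Da, geometric intensity decay) with apex
#' intensity proportional to its proportion. PTM spike-ins contribute
#' satellite envelopes at the modification's mass offset, scaled by
#' stoichiometry; a spike referencing an inapplicable modification (e.g. dY
#' on a Met-ending isotype) is an error. Noise peaks are uniform in m/z with
#' a minimum spacing of 1.5 Da so that noise can never form a valid
#' isotopic envelope (a simulator idealization that makes the envelope check
#' a meaningful discriminator).
#'
#' @param reporters \code{reporter_peptides} data.frame.
#' @param proportions named numeric vector (isotype id -> fraction).
#' @param ptm_spikes optional data.frame (\code{isotype, modification,
#'   stoichiometry}).
#' @param spectrum_params list; see \code{\link{simulation_manifest}}.
#' @param seed integer seed.
#' @return list with \code{peaks} (a \code{peak_list}) and \code{truth}
#'   (kind, isotype, modification, mono_mz, apex_intensity).
#' @export
simulate_spectrum <- function(reporters, proportions, ptm_spikes = NULL,
                              spectrum_params = list(), seed = 1) {
  sp <- utils::modifyList(list(n_noise_peaks = 50L,
                               noise_mz_range = c(3000, 4400),
                               intensity_scale = 100,
                               envelope_decay = 0.7,
                               noise_intensity_max = 1), spectrum_params)
  stopifnot("theoretical_mh" %in% names(reporters))
  active <- names(proportions)[proportions > 0]
  miss <- setdiff(active, reporters$isotype_id)
  if (length(miss)) stop("unknown isotypes in proportions: ",
                         paste(miss, collapse = ", "))
  mz <- numeric(0); int <- numeric(0)
  truth <- list()
  emit_envelope <- function(mono, apex) {
    k <- 0:3
    list(mz = mono + k * ISOTOPE_SPACING,
         int = apex * sp$envelope_decay^k)
  }
  apex_of <- stats::setNames(rep(NA_real_, length(active)), active)
  for (id in active) {
    mh <- reporters$theoretical_mh[reporters$isotype_id == id][1]
    apex <- sp$intensity_scale * proportions[[id]]
    apex_of[[id]] <- apex
    e <- emit_envelope(mh, apex)
    mz <- c(mz, e$mz); int <- c(int, e$int)
    truth <- c(truth, list(data.frame(kind = "reporter", isotype = id,
                                      modification = "unmodified",
                                      mono_mz = mh, apex_intensity = apex)))
  }
  if (!is.null(ptm_spikes) && nrow(ptm_spikes)) {
    mods <- standard_modifications()
    for (i in seq_len(nrow(ptm_spikes))) {
      id <- ptm_spikes$isotype[i]; mod <- ptm_spikes$modification[i]
      rp <- reporters[reporters$isotype_id == id, , drop = FALSE][1, ]
      mrow <- mods[mods$name == mod, , drop = FALSE]
      if (nrow(mrow) == 0L) stop("unknown modification: ", mod)
      if (!.mod_applies(mod, rp$sequence, rp$terminal_met))
        stop("modification ", mod, " does not apply to ", id)
      base_apex <- if (id %in% active) apex_of[[id]] else sp$intensity_scale
      apex <- base_apex * ptm_spikes$stoichiometry[i]
      e <- emit_envelope(rp$theoretical_mh + mrow$mass_delta, apex)
      mz <- c(mz, e$mz); int <- c(int, e$int)
      truth <- c(truth, list(data.frame(kind = "ptm_spike", isotype = id,
                                        modification = mod,
                                        mono_mz = rp$theoretical_mh + mrow$mass_delta,
                                        apex_intensity = apex)))
    }
  }
  pl <- .with_seed(.stage_seed(seed, "spectrum"), {
    nmz <- numeric(0)
    tries <- 0L
    while (length(nmz) < sp$n_noise_peaks && tries < 50L) {
      tries <- tries + 1L
      cand <- sort(c(nmz, stats::runif(sp$n_noise_peaks - length(nmz),
                                       sp$noise_mz_range[1],
                                       sp$noise_mz_range[2])))
      keep <- c(TRUE, diff(cand) >= 1.5)
      nmz <- cand[keep]
    }
    nint <- stats::runif(length(nmz), 0, sp$noise_intensity_max)
    peak_list(c(mz, nmz), c(int, nint),
              source_id = sprintf("sim_seed%d", as.integer(seed)))
  })
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(), isotype = character(),
               modification = character(), mono_mz = numeric(),
               apex_intensity = numeric())
  list(peaks = pl, truth = truth)
}

#' Simulate a complete dataset from a manifest
#'
#' Builds the synthetic transcript family for the packaged catalog, extracts
#' hypervariable reference regions, simulates stranded reads from the
#' transcript mixture and a MALDI peak list from the reporter mixture.
#'
#' Regions are placed to cover the divergent C-terminal coding tail plus the
#' isotype-specific 3'-UTR (\code{cds_tail_bp = 60}, \code{utr_bp = 140} by
#' default): extending further into the conserved reporter prefix would only
#' recruit ambiguous alignments, which the 3'-anchored region design exists
#' to avoid.
#'
#' @param manifest a \code{simulation_manifest}.
#' @param catalog an \code{isotype_catalog} (default: packaged
#'   \emph{P. deltoides} records).
#' @param reporters optional precomputed \code{reporter_peptides}.
#' @param cds_tail_bp,utr_bp region placement (see
#'   \code{\link{extract_region}}).
#' @return list with \code{regions} (named character), \code{reads},
#'   \code{read_truth}, \code{peaks}, \code{spectrum_truth},
#'   \code{manifest_hash}.
#' @export
simulate_dataset <- function(manifest, catalog = pd_catalog(),
                             reporters = NULL, cds_tail_bp = 60,
                             utr_bp = 140) {
  stopifnot(inherits(manifest, "simulation_manifest"))
  if (is.null(reporters))
    reporters <- suppressMessages(reporter_peptides(catalog))
  fam <- make_transcript_family(catalog, utr_len = utr_bp,
                                seed = manifest$seed)
  regions <- stats::setNames(vapply(seq_len(nrow(fam)), function(i)
    extract_region(fam$transcript[i], fam$stop_pos[i],
                   cds_tail_bp = cds_tail_bp, utr_bp = utr_bp,
                   isotype_id = fam$isotype_id[i])$sequence,
    character(1)), fam$isotype_id)
  rd <- simulate_reads(regions, manifest$isotype_proportions,
                       n_reads = manifest$read_params$n_reads,
                       read_length = manifest$read_params$read_length,
                       error_rate = manifest$read_params$error_rate,
                       seed = manifest$seed)
  sx <- simulate_spectrum(reporters, manifest$isotype_proportions,
                          ptm_spikes = manifest$ptm_spikes,
                          spectrum_params = manifest$spectrum_params,
                          seed = manifest$seed)
  list(regions = regions, reads = rd$reads, read_truth = rd$truth,
       peaks = sx$peaks, spectrum_truth = sx$truth,
       manifest_hash = manifest_hash(manifest))
}
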