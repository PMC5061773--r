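# PTM isoform enumeration and spectrum scanning.

#' Standard C-terminal PTM set
#'
#' Mass deltas are taken from the residue-mass table: detyrosination (dY)
#' removes the C-terminal Tyr, non-tyrosination (dEY) additionally removes
#' the penultimate Glu, glutamylation adds n Glu residues (+n x 129.0426 Da),
#' and Lys acetylation adds +42.0106 Da. Applicability is sequence-gated:
#' dY/dEY require a genome-encoded ...Y / ...EY C-terminus (isotypes ending
#' in Met, Glu or Gln cannot take part in the tyrosination cycle),
#' glutamylation requires an acidic (E/D) C-terminal tail, acetylation a Lys.
#'
#' @param mods character subset of \code{c("unmodified","dY","dEY",
#'   "glutamylation","acetylation")}.
#' @param max_glu maximum number of added Glu residues scanned (default 3).
#' @return data.frame with columns \code{name, n_glu, mass_delta}.
#' @export
standard_modifications <- function(mods = c("unmodified", "dY", "dEY",
                                            "glutamylation", "acetylation"),
                                   max_glu = 3) {
  mods <- match.arg(mods, several.ok = TRUE)
  rm <- mass_table()$residue_mass
  rows <- list()
  if ("unmodified" %in% mods)
    rows <- c(rows, list(c("unmodified", 0, 0)))
  if ("dY" %in% mods)
    rows <- c(rows, list(c("dY", 0, -rm[["Y"]])))
  if ("dEY" %in% mods)
    rows <- c(rows, list(c("dEY", 0, -rm[["E"]] - rm[["Y"]])))
  if ("glutamylation" %in% mods)
    for (n in seq_len(max_glu))
      rows <- c(rows, list(c(sprintf("glutamylation+%dE", n), n, n * rm[["E"]])))
  if ("acetylation" %in% mods)
    rows <- c(rows, list(c("acetylation", 0, 42.010565)))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("name", "n_glu", "mass_delta")
  out$n_glu <- as.integer(out$n_glu)
  out$mass_delta <- as.numeric(out$mass_delta)
  out
}

.mod_applies <- function(mod_name, sequence, terminal_met) {
  # the printed letters end in M for terminal-Met peptides, so the encoded
  # C-terminus test on the sequence string is already correct
  if (mod_name == "unmodified") return(rep(TRUE, length(sequence)))
  if (mod_name == "dY") return(endsWith(sequence, "Y") & !terminal_met)
  if (mod_name == "dEY") return(endsWith(sequence, "EY") & !terminal_met)
  if (startsWith(mod_name, "glutamylation")) return(grepl("[ED]", sequence))
  if (mod_name == "acetylation") return(grepl("K", sequence))
  stop("unknown modification: ", mod_name)
}

#' Enumerate PTM isoforms of reporter peptides
#'
#' Cartesian product of peptides and modifications, filtered by the
#' applicability predicate of each modification; every isoform carries
#' \code{expected_mh = theoretical_mh + mass_delta}. The unmodified isoform
#' is always included.
#'
#' @param peptides \code{reporter_peptides} data.frame (see
#'   \code{\link{reporter_peptides}}).
#' @param mods modification table from \code{\link{standard_modifications}}.
#' @return data.frame of class \code{ptm_isoforms} with columns
#'   \code{isotype_id, sequence, modification, mass_delta, base_mh,
#'   expected_mh}.
#' @export
#' @examples
#' rp <- reporter_peptides(pd_catalog())
#' iso <- enumerate_isoforms(rp[rp$isotype_id == "TUA1", ],
#'                           standard_modifications(c("unmodified", "dY", "dEY")))
#' round(iso$expected_mh, 3)
enumerate_isoforms <- function(peptides, mods = standard_modifications()) {
  stopifnot(nrow(peptides) > 0, "theoretical_mh" %in% names(peptides))
  if (!"unmodified" %in% mods$name)
    mods <- rbind(data.frame(name = "unmodified", n_glu = 0L, mass_delta = 0),
                  mods)
  out <- do.call(rbind, lapply(seq_len(nrow(mods)), function(i) {
    ok <- .mod_applies(mods$name[i], peptides$sequence, peptides$terminal_met)
    if (!any(ok)) return(NULL)
    p <- peptides[ok, , drop = FALSE]
    data.frame(isotype_id = p$isotype_id, sequence = p$sequence,
               modification = mods$name[i], mass_delta = mods$mass_delta[i],
               base_mh = p$theoretical_mh,
               expected_mh = p$theoretical_mh + mods$mass_delta[i],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("ptm_isoforms", "data.frame")
  out
}

#' Scan a peak list for PTM isoforms
#'
#' For each isoform the nearest peak within \code{tolerance} of its expected
#' MH+ is sought. The verdict is \code{"detected"} when such a peak exists,
#' its isotopic envelope validates (\code{\link{envelope_ok}}), and its
#' intensity clears the per-spectrum signal floor (median + 3 x MAD of peak
#' intensities); \code{"background"} when a peak matches but fails the
#' envelope or floor test; \code{"absent"} when no peak matches. Verdicts are
#' deterministic given the inputs.
#'
#' @param peaks a \code{peak_list} (or data.frame with sorted \code{mz},
#'   \code{intensity}).
#' @param isoforms \code{ptm_isoforms} from \code{\link{enumerate_isoforms}}.
#' @param tolerance matching tolerance in Da (default 0.3, linear-TOF scale
#'   for ~4 kDa peptides).
#' @param ratio_band allowed first-isotopologue/monoisotopic intensity ratio
#'   band for envelope validation.
#' @param floor_k multiplier on the MAD in the signal floor.
#' @return data.frame with \code{isotype_id, modification, expected_mh,
#'   matched_mz, intensity, verdict, mass_conflict}. \code{mass_conflict} is
#'   TRUE for a modified isoform whose expected mass falls within
#'   \code{2 * tolerance} of another isotype's unmodified reporter mass (e.g.
#'   TUB17 + 2 Glu coincides exactly with the TUB18 reporter); at such m/z a
#'   match cannot be attributed to the PTM and should not be counted as a
#'   detection.
#' @export
scan_spectrum <- function(peaks, isoforms, tolerance = 0.3,
                          ratio_band = c(0.3, 3.0), floor_k = 3) {
  stopifnot(tolerance > 0)
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) > 1 && any(diff(peaks$mz) <= 0))
    stop("peaks must be sorted by strictly increasing m/z")
  floor <- if (nrow(peaks)) {
    stats::median(peaks$intensity) + floor_k * stats::mad(peaks$intensity)
  } else Inf
  n <- nrow(isoforms)
  matched_mz <- rep(NA_real_, n); intensity <- rep(NA_real_, n)
  verdict <- rep("absent", n)
  if (nrow(peaks)) {
    for (i in seq_len(n)) {
      j <- .nearest_peak(peaks$mz, isoforms$expected_mh[i], tolerance)
      if (is.na(j)) next
      matched_mz[i] <- peaks$mz[j]
      intensity[i] <- peaks$intensity[j]
      ok <- envelope_ok(peaks, peaks$mz[j], tolerance, ratio_band = ratio_band)
      verdict[i] <- if (ok && peaks$intensity[j] >= floor) "detected" else "background"
    }
  }
  unmod <- isoforms[isoforms$modification == "unmodified", ]
  conflict <- vapply(seq_len(n), function(i) {
    if (isoforms$modification[i] == "unmodified") return(FALSE)
    other <- unmod$expected_mh[unmod$isotype_id != isoforms$isotype_id[i]]
    length(other) > 0 && any(abs(other - isoforms$expected_mh[i]) < 2 * tolerance)
  }, logical(1))
  data.frame(isotype_id = isoforms$isotype_id,
             modification = isoforms$modification,
             expected_mh = isoforms$expected_mh,
             matched_mz = matched_mz, intensity = intensity,
             verdict = verdict, mass_conflict = conflict,
             stringsAsFactors = FALSE)
}

# index of the peak nearest to target within tol, NA if none
.nearest_peak <- function(mz, target, tol) {
  j <- findInterval(target, mz)
  cand <- c(j, j + 1L)
  cand <- cand[cand >= 1L & cand <= length(mz)]
  if (!length(cand)) return(NA_integer_)
  d <- abs(mz[cand] - target)
  k <- cand[which.min(d)]
  if (abs(mz[k] - target) <= tol) k else NA_integer_
}
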