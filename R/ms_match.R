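# Peak-list model, isotopic-envelope validation, label-free quantification.

ISOTOPE_SPACING <- 1.00235  # Da, mean spacing of peptide isotopologues

#' Construct a MALDI peak list
#'
#' Peaks are sorted by m/z; exact m/z ties are merged by summing intensity.
#' Intensities must be non-negative.
#'
#' @param mz numeric m/z values (Da).
#' @param intensity matching non-negative intensities (arbitrary units).
#' @param source_id free-text provenance tag.
#' @param polarity ion mode; only positive mode is modelled.
#' @return data.frame of class \code{peak_list} with sorted columns
#'   \code{mz}, \code{intensity}.
#' @export
peak_list <- function(mz, intensity, source_id = "", polarity = "positive") {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be >= 0")
  polarity <- match.arg(polarity)
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, mz, sum))
    mz <- sort(unique(mz))
  }
  out <- data.frame(mz = mz, intensity = intensity)
  attr(out, "source_id") <- source_id
  attr(out, "polarity") <- polarity
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Read / write a peak list as two-column TSV
#'
#' The on-disk format is a TSV with header \code{mz<TAB>intensity}.
#'
#' @param path file path.
#' @export
read_peak_list <- function(path) {
  df <- utils::read.delim(path)
  peak_list(df$mz, df$intensity, source_id = basename(path))
}

#' @rdname read_peak_list
#' @param peaks a \code{peak_list}.
#' @export
write_peak_list <- function(peaks, path) {
  utils::write.table(as.data.frame(peaks)[, c("mz", "intensity")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Isotopic-envelope validation
#'
#' A candidate monoisotopic peak is accepted as genuine peptide signal only
#' if peaks exist within \code{tolerance} of \code{mono_mz + k * 1.00235} for
#' k = 0, 1, 2 (three consecutive isotopologues) and the k = 1 intensity lies
#' within \code{ratio_band} of the k = 0 intensity. For ~4 kDa peptides the
#' first isotopologue is comparable to the monoisotopic peak, hence the wide
#' default band of 0.3-3. Lone peaks, however well placed in m/z, are deemed
#' background.
#'
#' In addition, the candidate must actually be monoisotopic: if a peak sits
#' one isotope spacing \emph{below} it with at least \code{mono_veto} of its
#' intensity, the candidate is taken to be an interior isotopologue of a
#' larger envelope (e.g. another isotype's reporter one or two isotopes away)
#' and is rejected. Genuinely co-eluting isotypes whose masses differ by
#' almost exactly 1-2 isotope spacings can defeat this check; that mass
#' degeneracy is inherent to linear-TOF data.
#'
#' @param peaks a \code{peak_list} (or sorted data.frame).
#' @param mono_mz candidate monoisotopic m/z (Da).
#' @param tolerance matching tolerance (Da).
#' @param ratio_band numeric length-2, allowed k1/k0 intensity ratio.
#' @param mono_veto reject when the peak one spacing below holds at least
#'   this fraction of the candidate's intensity (default 0.5).
#' @return logical.
#' @export
#' @examples
#' pl <- peak_list(4180.69 + 1.00235 * 0:2, c(1, 0.8, 0.5))
#' envelope_ok(pl, 4180.69, 0.3)
envelope_ok <- function(peaks, mono_mz, tolerance, ratio_band = c(0.3, 3.0),
                        mono_veto = 0.5) {
  stopifnot(tolerance > 0)
  peaks <- as.data.frame(peaks)
  if (!nrow(peaks)) return(FALSE)
  idx <- vapply(0:2, function(k)
    .nearest_peak(peaks$mz, mono_mz + k * ISOTOPE_SPACING, tolerance),
    integer(1))
  if (anyNA(idx)) return(FALSE)
  left <- .nearest_peak(peaks$mz, peaks$mz[idx[1]] - ISOTOPE_SPACING, tolerance)
  if (!is.na(left) &&
      peaks$intensity[left] >= mono_veto * peaks$intensity[idx[1]])
    return(FALSE)
  ratio <- peaks$intensity[idx[2]] / peaks$intensity[idx[1]]
  is.finite(ratio) && ratio >= ratio_band[1] && ratio <= ratio_band[2]
}

# summed intensity of the validated k = 0..2 envelope, or 0
.envelope_intensity <- function(peaks, mono_mz, tolerance, ratio_band) {
  if (!envelope_ok(peaks, mono_mz, tolerance, ratio_band)) return(0)
  idx <- vapply(0:2, function(k)
    .nearest_peak(peaks$mz, mono_mz + k * ISOTOPE_SPACING, tolerance),
    integer(1))
  sum(peaks$intensity[idx])
}

#' Label-free relative quantification of tubulin isotypes
#'
#' Each reporter peptide contributes the summed intensity of its validated
#' isotopic envelope (k = 0..2), anchored at the peak nearest its theoretical
#' MH+; reporters without a validated envelope contribute 0. Mass-degenerate
#' reporters (theoretical masses closer than \code{2 * tolerance}, e.g. the
#' TUA4/TUA5 pair) are merged into one ambiguity group labelled like
#' \code{"TUA4/5"}. Relative abundances are normalized within each family
#' (TUA and TUB separately); cross-family comparison should use
#' \code{raw_intensity}.
#'
#' Optional transcript evidence (named FPKM vector) disambiguates a group:
#' when exactly one member's within-family FPKM share exceeds
#' \code{min_transcript_share} the group is relabelled to that member, with a
#' message, mirroring the reassignment of the TUA4/5 signal to TUA5 when
#' TUA4 transcripts are barely detected.
#'
#' @param peaks a \code{peak_list}.
#' @param reporters \code{reporter_peptides} data.frame.
#' @param tolerance matching tolerance (Da, default 0.3).
#' @param ratio_band envelope intensity ratio band.
#' @param transcript_evidence optional named numeric vector of FPKM by
#'   isotype id.
#' @param min_transcript_share minimum within-family FPKM share for a group
#'   member to be considered expressed (default 0.05).
#' @return data.frame of class \code{isotype_abundance} with columns
#'   \code{group, members, family, expected_mh, raw_intensity,
#'   relative_abundance}; attribute \code{no_signal} lists families with no
#'   detected reporter signal (their fractions are NA).
#' @export
quantify_isotypes <- function(peaks, reporters, tolerance = 0.3,
                              ratio_band = c(0.3, 3.0),
                              transcript_evidence = NULL,
                              min_transcript_share = 0.05) {
  if (is.null(reporters) || nrow(reporters) == 0L) stop("empty reporter catalog")
  stopifnot(tolerance > 0)
  groups <- .mass_groups(reporters, 2 * tolerance)
  raw <- vapply(groups, function(g)
    .envelope_intensity(peaks, mean(reporters$theoretical_mh[g]),
                        tolerance, ratio_band), numeric(1))
  fam <- vapply(groups, function(g) reporters$family[g[1]], character(1))
  members <- vapply(groups, function(g)
    paste(sort(reporters$isotype_id[g]), collapse = ","), character(1))
  label <- vapply(groups, function(g) .group_label(reporters$isotype_id[g]),
                  character(1))
  mh <- vapply(groups, function(g) mean(reporters$theoretical_mh[g]), numeric(1))

  if (!is.null(transcript_evidence)) {
    for (i in which(lengths(groups) > 1)) {
      ids <- reporters$isotype_id[groups[[i]]]
      fpkm <- transcript_evidence[ids]
      fpkm[is.na(fpkm)] <- 0
      fam_ids <- reporters$isotype_id[reporters$family == fam[i]]
      tot <- sum(transcript_evidence[names(transcript_evidence) %in% fam_ids])
      share <- if (tot > 0) fpkm / tot else rep(0, length(fpkm))
      expressed <- share >= min_transcript_share
      if (sum(expressed) == 1L) {
        message("ambiguity group ", label[i], " reassigned to ",
                ids[expressed], " on transcript evidence")
        label[i] <- ids[expressed]
      }
    }
  }

  rel <- rep(NA_real_, length(raw))
  no_signal <- character()
  for (f in unique(fam)) {
    sel <- fam == f
    tot <- sum(raw[sel])
    if (tot > 0) rel[sel] <- raw[sel] / tot else no_signal <- c(no_signal, f)
  }
  out <- data.frame(group = label, members = members, family = fam,
                    expected_mh = mh, raw_intensity = raw,
                    relative_abundance = rel, stringsAsFactors = FALSE)
  attr(out, "no_signal") <- no_signal
  class(out) <- c("isotype_abundance", "data.frame")
  out
}

# connected components of reporters whose masses are closer than gap,
# within family
.mass_groups <- function(reporters, gap) {
  groups <- list()
  for (f in unique(reporters$family)) {
    idx <- which(reporters$family == f)
    idx <- idx[order(reporters$theoretical_mh[idx])]
    mh <- reporters$theoretical_mh[idx]
    brk <- c(0L, which(diff(mh) >= gap), length(idx))
    for (i in seq_len(length(brk) - 1L))
      groups <- c(groups, list(idx[(brk[i] + 1L):brk[i + 1L]]))
  }
  groups
}

# "TUA4/5"-style label for a degenerate group
.group_label <- function(ids) {
  if (length(ids) == 1L) return(ids)
  ids <- sort(ids)
  nums <- sub("^TU[AB]", "", ids)
  paste0(ids[1], "/", paste(nums[-1], collapse = "/"))
}
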