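# Paralog-aware transcript quantification against hypervariable C-terminal
# reference regions: glocal read mapping with coverage/mismatch filters,
# best-hit assignment, FPKM, and protein/transcript concordance.

#' Extract a hypervariable C-terminal reference region
#'
#' Returns the last \code{cds_tail_bp} bases of coding sequence concatenated
#' with the first \code{utr_bp} bases of 3'-UTR (truncated at the transcript
#' ends, with a warning). Regions of up to 200 bp covering the hypervariable
#' C-terminus plus a portion of UTR minimize ambiguous alignment among
#' near-identical paralogs.
#'
#' @param transcript nucleotide string (A/C/G/T).
#' @param stop_pos 1-based position of the last coding base.
#' @param cds_tail_bp coding bases to keep upstream of \code{stop_pos}.
#' @param utr_bp UTR bases to keep downstream.
#' @param isotype_id optional region id.
#' @return list with \code{isotype_id, sequence, start, end, length_bp}.
#' @export
#' @examples
#' tr <- paste(rep("ACGT", 225), collapse = "")  # 900 bp
#' extract_region(tr, stop_pos = 840, cds_tail_bp = 120, utr_bp = 80)$start
extract_region <- function(transcript, stop_pos, cds_tail_bp = 110,
                           utr_bp = 90, isotype_id = NA_character_) {
  n <- nchar(transcript)
  stopifnot(stop_pos >= 1, stop_pos <= n)
  if (cds_tail_bp + utr_bp <= 0) stop("empty region requested")
  if (cds_tail_bp + utr_bp > 200)
    stop("region length capped at 200 bp")
  start <- stop_pos - cds_tail_bp + 1L
  end <- min(n, stop_pos + utr_bp)  # a short 3'-UTR is clipped silently
  if (start < 1L) {
    warning("region truncated at transcript start for ",
            if (is.na(isotype_id)) "transcript" else isotype_id)
    start <- 1L
  }
  list(isotype_id = isotype_id, sequence = substr(transcript, start, end),
       start = start, end = end, length_bp = end - start + 1L)
}

.as_dna_set <- function(x, prefix = "seq") {
  if (is(x, "DNAStringSet")) {
    if (is.null(names(x))) names(x) <- paste0(prefix, seq_along(x))
    return(x)
  }
  out <- Biostrings::DNAStringSet(unlist(x))
  if (is.null(names(out)) || !any(nzchar(names(out))))
    names(out) <- paste0(prefix, seq_along(out))
  out
}

# parse one vectorized glocal alignment into per-read stats (vectorized
# native accessors; read length L is needed to account for end overhangs,
# which appear neither in nindel nor in nmismatch)
.aln_stats <- function(pa, L) {
  ind <- Biostrings::nindel(pa)
  ins_w <- Biostrings::insertion(ind)[, "WidthSum"]  # read bases over region gaps
  del_w <- Biostrings::deletion(ind)[, "WidthSum"]   # region bases skipped
  s <- Biostrings::subject(pa)
  subj_w <- Biostrings::end(s) - Biostrings::start(s) + 1L
  aligned <- subj_w - del_w                          # read bases on region letters
  cbind(mism = Biostrings::nmismatch(pa),
        edits = Biostrings::nmismatch(pa) + ins_w + del_w,
        aligned = aligned)
}

#' Map reads to reference regions with best-hit assignment
#'
#' Each read is aligned glocally (read-global, region-local; match +1,
#' mismatch -1, gap open -2, gap extend -1) against every region, on both
#' strands unless \code{stranded}. Candidates failing read-length coverage
#' \code{> min_coverage} or edit operations (mismatches plus gap columns)
#' \code{<= floor(max_mismatch_frac * read length)} are filtered; among
#' survivors the unique top score is \code{assigned}, equal top scores on
#' different regions give \code{ambiguous_tie} and the read is discarded from
#' counting. Reads whose best candidate fails a filter are classed
#' \code{filtered_coverage} / \code{filtered_mismatch}; reads with no
#' plausible candidate (no clean 15-bp seed window on any region, or best
#' score <= 0) are \code{unmapped}.
#'
#' Internally, exact full-length matches are resolved with
#' \code{Biostrings::PDict}; only inexact reads reach the dynamic-programming
#' aligner, restricted to regions sharing a seed window with the read.
#'
#' @param reads named character vector or \code{DNAStringSet} (length >= 20 nt).
#' @param regions named character vector or \code{DNAStringSet} of reference
#'   regions.
#' @param max_mismatch_frac mismatch allowance as a fraction of read length
#'   (default 0.02).
#' @param min_coverage minimum read-length coverage fraction (default 0.95).
#' @param stranded if TRUE, only the forward strand is searched.
#' @return data.frame with one row per read: \code{read_id, region_id,
#'   strand, aligned_length, coverage_fraction, mismatches, score, status}.
#' @export
map_reads <- function(reads, regions, max_mismatch_frac = 0.02,
                      min_coverage = 0.95, stranded = FALSE) {
  reads <- .as_dna_set(reads, "read")
  regions <- .as_dna_set(regions, "region")
  if (length(regions) == 0L) stop("regions must be non-empty")
  if (any(Biostrings::width(reads) < 20L)) stop("reads must be >= 20 nt")

  subjects <- regions
  strand <- rep("+", length(regions))
  sregion <- names(regions)
  if (!stranded) {
    subjects <- c(subjects, Biostrings::reverseComplement(regions))
    strand <- c(strand, rep("-", length(regions)))
    sregion <- c(sregion, names(regions))
  }

  n <- length(reads)
  L <- Biostrings::width(reads)
  res <- data.frame(read_id = names(reads), region_id = NA_character_,
                    strand = NA_character_, aligned_length = NA_integer_,
                    coverage_fraction = NA_real_, mismatches = NA_integer_,
                    score = NA_real_, status = "unmapped",
                    stringsAsFactors = FALSE)

  # ---- exact full-length matches (fast path) --------------------------------
  exact <- matrix(FALSE, n, length(subjects))
  for (w in unique(L)) {
    sel <- which(L == w)
    pd <- Biostrings::PDict(reads[sel])
    hit <- Biostrings::vcountPDict(pd, subjects) > 0L
    exact[sel, ] <- hit
  }
  exact_regions <- lapply(seq_len(n), function(i)
    unique(sregion[exact[i, ]]))
  done <- logical(n)
  for (i in seq_len(n)) {
    er <- exact_regions[[i]]
    if (length(er) == 1L) {
      j <- which(exact[i, ])[1]
      res[i, c("region_id", "strand")] <- c(sregion[j], strand[j])
      res$aligned_length[i] <- L[i]; res$coverage_fraction[i] <- 1
      res$mismatches[i] <- 0L; res$score[i] <- L[i]
      res$status[i] <- "assigned"; done[i] <- TRUE
    } else if (length(er) > 1L) {
      res$status[i] <- "ambiguous_tie"; done[i] <- TRUE
    }
  }

  # ---- seeded inexact alignment ---------------------------------------------
  todo <- which(!done)
  if (length(todo)) {
    w <- 15L
    seed_read <- integer(0); seed_seq <- character(0)
    rc <- as.character(reads[todo])
    for (i in seq_along(todo)) {
      offs <- seq(1L, L[todo[i]] - w + 1L, by = w)
      seed_read <- c(seed_read, rep(todo[i], length(offs)))
      seed_seq <- c(seed_seq, substring(rc[i], offs, offs + w - 1L))
    }
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_seq))
    hits <- Biostrings::vwhichPDict(pd, subjects)
    cand <- vector("list", n)  # candidate subject indices per read
    for (j in seq_along(subjects)) {
      rid <- unique(seed_read[hits[[j]]])
      for (i in rid) cand[[i]] <- c(cand[[i]], j)
    }
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = TRUE)
    best <- vector("list", n)
    for (j in seq_along(subjects)) {
      ridx <- todo[vapply(todo, function(i) j %in% cand[[i]], logical(1))]
      if (!length(ridx)) next
      pa <- Biostrings::pairwiseAlignment(reads[ridx], subjects[[j]],
                                          type = "global-local",
                                          substitutionMatrix = mat,
                                          gapOpening = 2, gapExtension = 1)
      st <- .aln_stats(pa, L[ridx])
      sc <- Biostrings::score(pa)
      for (k in seq_along(ridx)) {
        i <- ridx[k]
        rec <- c(subject = j, score = unname(sc[k]),
                 edits = unname(st[k, "edits"]),
                 aligned = unname(st[k, "aligned"]))
        best[[i]] <- c(best[[i]], list(rec))
      }
    }
    for (i in todo) {
      cands <- best[[i]]
      if (is.null(cands)) next  # stays unmapped
      scores <- vapply(cands, `[[`, numeric(1), "score")
      edits <- vapply(cands, `[[`, numeric(1), "edits")
      alen <- vapply(cands, `[[`, numeric(1), "aligned")
      cov <- alen / L[i]
      pass <- cov > min_coverage & edits <= floor(max_mismatch_frac * L[i])
      if (any(pass)) {
        top <- max(scores[pass])
        top_regions <- unique(sregion[vapply(cands[pass & scores == top],
                                             `[[`, numeric(1), "subject")])
        k <- which(pass & scores == top)[1]
        if (length(top_regions) > 1L) {
          res$status[i] <- "ambiguous_tie"
        } else {
          j <- cands[[k]][["subject"]]
          res[i, c("region_id", "strand")] <- c(sregion[j], strand[j])
          res$aligned_length[i] <- alen[k]
          res$coverage_fraction[i] <- cov[k]
          res$mismatches[i] <- as.integer(edits[k])
          res$score[i] <- scores[k]
          res$status[i] <- "assigned"
        }
      } else {
        k <- which.max(scores)
        if (scores[k] <= 0) next  # unmapped: no plausible alignment
        res$aligned_length[i] <- alen[k]
        res$coverage_fraction[i] <- cov[k]
        res$mismatches[i] <- as.integer(edits[k])
        res$score[i] <- scores[k]
        res$status[i] <- if (cov[k] <= min_coverage) "filtered_coverage"
                         else "filtered_mismatch"
      }
    }
  }
  res
}

#' @rdname map_reads
#' @param read a single read (string).
#' @export
map_read <- function(read, regions, max_mismatch_frac = 0.02,
                     min_coverage = 0.95, stranded = FALSE) {
  map_reads(stats::setNames(as.character(read), "read1"), regions,
            max_mismatch_frac, min_coverage, stranded)
}

#' Fragments per kilobase of region per million total reads
#'
#' Counts only \code{status == "assigned"} alignments;
#' \code{fpkm = assigned / (length_bp/1000) / (total_reads/1e6)}. One record
#' is emitted per region, including zeros.
#'
#' @param alignments data.frame from \code{\link{map_reads}}.
#' @param regions named character vector or \code{DNAStringSet} of the
#'   regions used for mapping.
#' @param total_reads total reads in the library (> 0).
#' @return data.frame with \code{isotype_id, length_bp, assigned, fpkm}.
#' @export
#' @examples
#' aln <- data.frame(region_id = rep("TUB15", 100), status = "assigned")
#' compute_fpkm(aln, c(TUB15 = paste(rep("A", 200), collapse = "")), 1e6)$fpkm
compute_fpkm <- function(alignments, regions, total_reads) {
  if (length(total_reads) != 1L || total_reads <= 0)
    stop("total_reads must be a positive count")
  regions <- .as_dna_set(regions, "region")
  assigned <- alignments$region_id[alignments$status == "assigned"]
  counts <- table(factor(assigned, levels = names(regions)))
  len <- Biostrings::width(regions)
  data.frame(isotype_id = names(regions), length_bp = len,
             assigned = as.integer(counts),
             fpkm = as.integer(counts) / (len / 1000) / (total_reads / 1e6),
             stringsAsFactors = FALSE)
}

#' Protein/transcript concordance report
#'
#' Joins isotype-level protein abundances and transcript FPKM on shared
#' isotype ids and computes a Spearman rank correlation per family. An
#' isotype is flagged discordant when its transcript sits in the top quartile
#' of its family while its protein falls at or below the family median --
#' the pattern shown by TUB17/TUB18, whose transcripts are abundant but whose
#' reporter-peptide signals are low.
#'
#' @param protein data.frame with \code{isotype_id} (or \code{group}),
#'   \code{family}, and \code{relative_abundance} or \code{raw_intensity}.
#' @param transcript data.frame with \code{isotype_id} and \code{fpkm}.
#' @param transcript_quartile transcript percentile above which an isotype
#'   counts as highly expressed (default 0.75).
#' @param protein_median protein percentile at or below which it counts as
#'   under-translated (default 0.5).
#' @return list with \code{by_family} (family, n, spearman) and
#'   \code{per_isotype} (ranks, percentiles, \code{flagged}).
#' @export
concordance_report <- function(protein, transcript,
                               transcript_quartile = 0.75,
                               protein_median = 0.5) {
  pid <- if ("isotype_id" %in% names(protein)) protein$isotype_id else protein$group
  pval <- if ("relative_abundance" %in% names(protein))
    protein$relative_abundance else protein$raw_intensity
  df <- merge(data.frame(isotype_id = pid, family = protein$family,
                         protein = pval, stringsAsFactors = FALSE),
              transcript[, c("isotype_id", "fpkm")], by = "isotype_id")
  df <- df[!is.na(df$protein) & !is.na(df$fpkm), ]
  fams <- unique(df$family)
  by_family <- data.frame(family = fams, n = NA_integer_,
                          spearman = NA_real_, stringsAsFactors = FALSE)
  df$protein_pct <- NA_real_; df$transcript_pct <- NA_real_
  for (k in seq_along(fams)) {
    sel <- df$family == fams[k]
    n <- sum(sel)
    by_family$n[k] <- n
    if (n < 3L) {
      warning("fewer than 3 shared isotypes in family ", fams[k],
              "; correlation omitted")
    } else {
      by_family$spearman[k] <- stats::cor(df$protein[sel], df$fpkm[sel],
                                          method = "spearman")
    }
    df$protein_pct[sel] <- rank(df$protein[sel]) / n
    df$transcript_pct[sel] <- rank(df$fpkm[sel]) / n
  }
  df$flagged <- df$transcript_pct > transcript_quartile &
    df$protein_pct <= protein_median
  list(by_family = by_family, per_isotype = df)
}
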