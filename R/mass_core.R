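# Monoisotopic mass arithmetic and in silico digestion.

.mass_env <- new.env(parent = emptyenv())

#' Monoisotopic mass constants
#'
#' Residue masses are read once from the versioned constants file shipped in
#' \code{inst/extdata/residue_masses.tsv} (standard monoisotopic values, Cys
#' unmodified). Water and proton masses are fixed; candidate conventions for
#' the CNBr-converted terminal Met are exposed so that
#' \code{\link{resolve_met_convention}} can select one against printed data.
#'
#' @return A list with elements \code{residue_mass} (named numeric, Da),
#'   \code{water}, \code{proton}, and \code{met_deltas} (named numeric:
#'   \code{homoserine_lactone}, \code{homoserine}, \code{unmodified}).
#' @export
#' @examples
#' mass_table()$residue_mass[["G"]]
mass_table <- function() {
  if (is.null(.mass_env$tab)) {
    path <- system.file("extdata", "residue_masses.tsv",
                        package = "tubulinptm", mustWork = TRUE)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    rm <- stats::setNames(df$mass, df$letter)
    stopifnot(all(rm > 50), all(rm < 200))
    .mass_env$tab <- list(
      residue_mass = rm,
      water  = 18.010565,
      proton = 1.007276,
      met_deltas = c(homoserine_lactone = -48.003371,
                     homoserine         = -29.992806,
                     unmodified         = 0))
  }
  .mass_env$tab
}

.check_aa <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  letters <- strsplit(sequence, "")[[1]]
  known <- names(mass_table()$residue_mass)
  bad <- which(!(letters %in% known))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", letters[bad[1]], bad[1]))
  letters
}

#' Singly protonated monoisotopic peptide mass (MH+)
#'
#' MH+ = sum of residue masses + H2O + one proton. When \code{terminal_met}
#' is TRUE the final residue must be Met and \code{met_delta} is added,
#' modelling the CNBr conversion of the cleaved Met (homoserine lactone by
#' default, i.e. -48.0034 Da).
#'
#' @param sequence amino-acid string (uppercase, 20-letter alphabet), or a
#'   character vector of such strings.
#' @param terminal_met logical, recycled along \code{sequence}.
#' @param met_delta mass delta (Da) applied to a CNBr-converted terminal Met.
#' @return numeric vector of MH+ values in Da (full precision; round only
#'   for display).
#' @export
#' @examples
#' peptide_mh("G")                                   # 76.039
#' peptide_mh("EEGEFSEAREDLAALEKDYEEVGAESPDGEDGDEGDEY")  # TUA1 reporter
peptide_mh <- function(sequence, terminal_met = FALSE,
                       met_delta = mass_table()$met_deltas[["homoserine_lactone"]]) {
  tab <- mass_table()
  n <- length(sequence)
  terminal_met <- rep_len(terminal_met, n)
  vapply(seq_len(n), function(i) {
    letters <- .check_aa(sequence[i])
    if (terminal_met[i] && letters[length(letters)] != "M")
      stop("terminal_met = TRUE but sequence does not end in M: ", sequence[i])
    sum(tab$residue_mass[letters]) + tab$water + tab$proton +
      if (terminal_met[i]) met_delta else 0
  }, numeric(1))
}

#' Resolve the terminal-Met mass convention against printed masses
#'
#' CNBr cleavage converts the cleaved Met; the convention used in a printed
#' reporter table (homoserine lactone, homoserine, or unmodified Met) is
#' recovered by brute force: the unique candidate delta under which every
#' terminal-Met peptide's computed MH+ matches its printed value within
#' \code{tol} is selected.
#'
#' @param peptides data.frame with columns \code{sequence},
#'   \code{terminal_met}, \code{printed_mh} (e.g. a catalog from
#'   \code{\link{load_catalog}}).
#' @param tol agreement tolerance in Da (default 0.01).
#' @return list with \code{convention} (name), \code{delta} (Da) and
#'   \code{residuals} (matrix, terminal-Met rows x candidates).
#' @export
resolve_met_convention <- function(peptides, tol = 0.01) {
  stopifnot(all(c("sequence", "terminal_met", "printed_mh") %in% names(peptides)))
  met <- peptides[peptides$terminal_met & !is.na(peptides$printed_mh), , drop = FALSE]
  if (nrow(met) == 0L)
    stop("no terminal-Met peptides with printed masses: nothing to resolve")
  deltas <- mass_table()$met_deltas
  res <- sapply(deltas, function(d)
    peptide_mh(met$sequence, terminal_met = TRUE, met_delta = d) - met$printed_mh)
  res <- matrix(res, nrow = nrow(met), dimnames = list(met$sequence, names(deltas)))
  fits <- apply(abs(res) <= tol, 2, all)
  if (sum(fits) != 1L) {
    report <- paste(sprintf("%s: max |residual| %.4f Da", names(deltas),
                            apply(abs(res), 2, max)), collapse = "; ")
    stop("no unique terminal-Met convention fits all printed masses (",
         report, ")")
  }
  conv <- names(deltas)[fits]
  message("terminal-Met convention resolved: ", conv,
          sprintf(" (delta %.6f Da, %d peptides)", deltas[[conv]], nrow(met)))
  list(convention = conv, delta = deltas[[conv]], residuals = res)
}

#' In silico protein digestion
#'
#' CNBr cleaves C-terminal to every Met; each fragment ending in Met carries
#' \code{terminal_met = TRUE} (the converted residue), including a
#' protein-terminal Met. Trypsin cleaves C-terminal to Lys/Arg except before
#' Pro, and cleavage is suppressed at positions listed in
#' \code{modified_positions} (e.g. an acetylated Lys-40 blocks the cut,
#' merging the flanking fragments).
#'
#' @param protein amino-acid string.
#' @param protease \code{"cnbr"} or \code{"trypsin"}.
#' @param modified_positions integer positions (1-based) of modified residues
#'   at which cleavage is blocked (trypsin only).
#' @return data.frame with columns \code{sequence}, \code{start}, \code{end},
#'   \code{terminal_met}; fragments partition the protein in order.
#' @export
#' @examples
#' digest("ACDMEFG", "cnbr")
digest <- function(protein, protease = c("cnbr", "trypsin"),
                   modified_positions = integer()) {
  protease <- match.arg(protease)
  letters <- .check_aa(protein)
  n <- length(letters)
  if (protease == "cnbr") {
    sites <- which(letters == "M")
  } else {
    sites <- which(letters %in% c("K", "R"))
    sites <- sites[sites == n | letters[pmin(sites + 1L, n)] != "P"]
    sites <- setdiff(sites, as.integer(modified_positions))
  }
  ends <- unique(c(sites[sites < n], n))
  starts <- c(1L, head(ends, -1L) + 1L)
  seqs <- substring(protein, starts, ends)
  data.frame(sequence = seqs, start = starts, end = ends,
             terminal_met = protease == "cnbr" & endsWith(seqs, "M"),
             stringsAsFactors = FALSE)
}
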