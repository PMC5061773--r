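# Isotype catalog: reporter-region records and standard-format I/O.

.validate_catalog <- function(df, source = "catalog") {
  need <- c("id", "family", "species_tag", "protein_seq",
            "span_start", "span_end", "terminal_met")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(source, " is missing columns: ", paste(miss, collapse = ", "))
  if (!"printed_mh" %in% names(df)) df$printed_mh <- NA_real_
  if (!"nt_region" %in% names(df)) df$nt_region <- NA_character_
  key <- paste(df$id, df$species_tag)
  if (anyDuplicated(key))
    stop("duplicate isotype record(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  known <- names(mass_table()$residue_mass)
  for (i in seq_len(nrow(df))) {
    letters <- strsplit(df$protein_seq[i], "")[[1]]
    if (length(letters) == 0L)
      stop("empty protein sequence in record ", df$id[i])
    bad <- !(letters %in% known)
    if (any(bad))
      stop(sprintf("non-amino-acid character '%s' in record %s",
                   letters[which(bad)[1]], df$id[i]))
    if (df$span_end[i] - df$span_start[i] + 1L != nchar(df$protein_seq[i]))
      stop("span does not match sequence length in record ", df$id[i])
  }
  if (!all(df$family %in% c("TUA", "TUB")))
    stop("family must be TUA or TUB")
  class(df) <- c("isotype_catalog", "data.frame")
  df
}

#' Load an isotype catalog from FASTA or TSV
#'
#' TSV files need columns \code{isotype, family, species, span_start,
#' span_end, sequence, terminal_met} (optionally \code{printed_mh},
#' \code{nt_region}). FASTA headers carry the same metadata as
#' \code{key=value} tags, e.g.
#' \code{>TUA1 species=Pd family=TUA span=414-451 terminal_met=0 printed_mh=4180.691}.
#' Per the reporter-table convention, \code{protein_seq} is the C-terminal
#' reporter region itself and \code{span} locates it in the full protein.
#'
#' @param path file path (\code{.tsv}/\code{.txt} or \code{.fa}/\code{.fasta}).
#' @return data.frame of class \code{isotype_catalog} with one row per
#'   (isotype, species) record.
#' @export
#' @examples
#' cat <- pd_catalog()
#' table(cat$family)
load_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt")) {
    if (file.size(path) == 0L || nrow(df <- utils::read.delim(path)) == 0L) {
      warning("empty catalog file: ", path)
      return(.empty_catalog())
    }
    out <- data.frame(id = df$isotype, family = df$family,
                      species_tag = df$species, protein_seq = df$sequence,
                      span_start = as.integer(df$span_start),
                      span_end = as.integer(df$span_end),
                      terminal_met = as.logical(df$terminal_met),
                      printed_mh = if ("printed_mh" %in% names(df))
                        as.numeric(df$printed_mh) else NA_real_,
                      nt_region = if ("nt_region" %in% names(df))
                        as.character(df$nt_region) else NA_character_,
                      stringsAsFactors = FALSE)
  } else if (ext %in% c("fa", "fasta", "faa")) {
    aas <- Biostrings::readAAStringSet(path)
    if (length(aas) == 0L) {
      warning("empty catalog file: ", path)
      return(.empty_catalog())
    }
    hdr <- names(aas)
    id <- sub("\\s.*$", "", hdr)
    tag <- function(key, default = NA_character_) {
      hit <- regexpr(paste0(key, "=[^ ]+"), hdr)
      val <- rep(NA_character_, length(hdr))
      ok <- hit > 0
      val[ok] <- substring(hdr[ok], hit[ok] + nchar(key) + 1L,
                           hit[ok] + attr(hit, "match.length")[ok] - 1L)
      fill <- rep_len(default, length(hdr))
      val[is.na(val)] <- fill[is.na(val)]
      val
    }
    span <- tag("span")
    out <- data.frame(id = id,
                      family = tag("family", substr(id, 1, 3)),
                      species_tag = tag("species", ""),
                      protein_seq = as.character(aas),
                      span_start = as.integer(sub("-.*", "", span)),
                      span_end = as.integer(sub(".*-", "", span)),
                      terminal_met = tag("terminal_met", "0") == "1",
                      printed_mh = suppressWarnings(as.numeric(tag("printed_mh"))),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  } else stop("unsupported catalog format: .", ext)
  .validate_catalog(out, source = path)
}

.empty_catalog <- function() {
  df <- data.frame(id = character(), family = character(),
                   species_tag = character(), protein_seq = character(),
                   span_start = integer(), span_end = integer(),
                   terminal_met = logical(), printed_mh = numeric(),
                   nt_region = character(), stringsAsFactors = FALSE)
  class(df) <- c("isotype_catalog", "data.frame")
  df
}

#' Packaged reporter catalogs
#'
#' The 28 isotype records (8 TUA + 20 TUB) of the \emph{P. deltoides}
#' reporter table, and the corresponding \emph{P. tremula x alba} records
#' (species variants share the isotype id; two have truncated spans).
#'
#' @return an \code{isotype_catalog}.
#' @export
pd_catalog <- function() {
  load_catalog(system.file("extdata", "reporter_table_pd.tsv",
                           package = "tubulinptm", mustWork = TRUE))
}

#' @rdname pd_catalog
#' @export
pta_catalog <- function() {
  load_catalog(system.file("extdata", "reporter_table_pta.tsv",
                           package = "tubulinptm", mustWork = TRUE))
}

#' Write an isotype catalog to TSV
#'
#' Inverse of \code{\link{load_catalog}} for the TSV layout; a
#' load-write-load round trip is the identity on records.
#'
#' @param catalog an \code{isotype_catalog}.
#' @param path output TSV path.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(isotype = catalog$id, family = catalog$family,
                   species = catalog$species_tag,
                   span_start = catalog$span_start,
                   span_end = catalog$span_end,
                   sequence = catalog$protein_seq,
                   terminal_met = catalog$terminal_met,
                   printed_mh = catalog$printed_mh)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reporter peptides with theoretical MH+
#'
#' Computes the theoretical singly protonated monoisotopic mass for every
#' record of a catalog. The terminal-Met delta is resolved from printed
#' masses when present (see \code{\link{resolve_met_convention}}), otherwise
#' the homoserine-lactone default applies.
#'
#' @param catalog an \code{isotype_catalog}.
#' @param met_delta optional terminal-Met delta override (Da).
#' @return data.frame of class \code{reporter_peptides} with columns
#'   \code{isotype_id, family, species_tag, span_start, span_end, sequence,
#'   terminal_met, theoretical_mh, printed_mh}.
#' @export
#' @examples
#' rp <- reporter_peptides(pd_catalog())
#' round(rp$theoretical_mh[rp$isotype_id == "TUA1"], 3)
reporter_peptides <- function(catalog, met_delta = NULL) {
  if (nrow(catalog) == 0L) stop("empty catalog")
  if (is.null(met_delta)) {
    met_delta <- if (any(catalog$terminal_met & !is.na(catalog$printed_mh))) {
      resolve_met_convention(data.frame(sequence = catalog$protein_seq,
                                        terminal_met = catalog$terminal_met,
                                        printed_mh = catalog$printed_mh))$delta
    } else mass_table()$met_deltas[["homoserine_lactone"]]
  }
  out <- data.frame(isotype_id = catalog$id, family = catalog$family,
                    species_tag = catalog$species_tag,
                    span_start = catalog$span_start,
                    span_end = catalog$span_end,
                    sequence = catalog$protein_seq,
                    terminal_met = catalog$terminal_met,
                    theoretical_mh = peptide_mh(catalog$protein_seq,
                                                catalog$terminal_met,
                                                met_delta = met_delta),
                    printed_mh = catalog$printed_mh,
                    stringsAsFactors = FALSE)
  attr(out, "met_delta") <- met_delta
  class(out) <- c("reporter_peptides", "data.frame")
  out
}

#' Write / read a reporter-peptide table
#'
#' TSV with columns \code{isotype, span, sequence, terminal_met, mh}; masses
#' are printed half-even rounded to 3 decimals, row order is preserved.
#'
#' @param peptides a \code{reporter_peptides} data.frame.
#' @param path output TSV path.
#' @export
write_reporter_table <- function(peptides, path) {
  if (nrow(peptides) == 0L) stop("no peptides to write")
  df <- data.frame(isotype = peptides$isotype_id,
                   span = sprintf("%d-%d", peptides$span_start, peptides$span_end),
                   sequence = peptides$sequence,
                   terminal_met = peptides$terminal_met,
                   mh = sprintf("%.3f", round(peptides$theoretical_mh, 3)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reporter_table
#' @export
read_reporter_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(isotype_id = df$isotype,
             span_start = as.integer(sub("-.*", "", df$span)),
             span_end = as.integer(sub(".*-", "", df$span)),
             sequence = df$sequence,
             terminal_met = as.logical(df$terminal_met),
             theoretical_mh = as.numeric(df$mh),
             stringsAsFactors = FALSE)
}
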