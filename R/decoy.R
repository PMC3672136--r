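#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet
NULL

# Accession prefix marking reversed decoy records. Fixed by convention so
# downstream stages can recognise decoys without side-channel metadata.
DECOY_PREFIX <- "REV_"

#' Read a protein FASTA file
#'
#' @param path FASTA file of amino acid sequences.
#' @return A named character vector, accession -> sequence. The accession is
#'   the first whitespace-delimited token of the header; the remainder is
#'   kept in the `descriptions` attribute.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  acc <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(aa)
  names(seqs) <- acc
  attr(seqs, "descriptions") <- stats::setNames(desc, acc)
  seqs
}

#' Write a protein FASTA file
#'
#' @param seqs Named character vector (accession -> sequence); an optional
#'   `descriptions` attribute is appended to headers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  desc <- attr(seqs, "descriptions")
  headers <- names(seqs)
  if (!is.null(desc)) {
    extra <- desc[headers]
    extra[is.na(extra)] <- ""
    headers <- ifelse(nzchar(extra), paste(headers, extra), headers)
  }
  aa <- Biostrings::AAStringSet(as.character(seqs))
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Build a concatenated target-decoy database
#'
#' Appends one reversed-sequence decoy record per target, with the accession
#' prefixed `REV_`. Searching spectra against the concatenated database lets
#' the decoy hit rate estimate the rate of incorrect matches, because an
#' incorrect match is (approximately) equally likely to land on a target or
#' a decoy sequence.
#'
#' @param targets Named character vector of target sequences
#'   (accession -> sequence), e.g. from [read_protein_fasta()].
#' @return Named character vector of length `2 * length(targets)`: all
#'   targets followed by their reversed decoys.
#' @examples
#' build_decoy_database(c(P1 = "MKLV"))
#' @export
build_decoy_database <- function(targets) {
  if (length(targets) == 0) stop("target database is empty")
  acc <- names(targets)
  if (is.null(acc) || any(!nzchar(acc))) stop("all targets must have accessions")
  if (anyDuplicated(acc)) {
    stop("duplicate accessions in target database: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  if (any(startsWith(acc, DECOY_PREFIX))) {
    stop("target accessions must not carry the decoy prefix '", DECOY_PREFIX, "'")
  }
  reversed <- vapply(strsplit(unname(targets), ""), function(x) {
    paste(rev(x), collapse = "")
  }, character(1))
  decoys <- stats::setNames(reversed, paste0(DECOY_PREFIX, acc))
  out <- c(targets, decoys)
  desc <- attr(targets, "descriptions")
  if (!is.null(desc)) {
    attr(out, "descriptions") <- c(desc,
      stats::setNames(paste("decoy (reversed)", acc), names(decoys)))
  }
  out
}

#' Is an accession a decoy accession?
#'
#' @param accession Character vector of accessions.
#' @return Logical vector: `TRUE` where the accession carries the `REV_`
#'   decoy prefix.
#' @export
is_decoy_accession <- function(accession) {
  startsWith(accession, DECOY_PREFIX)
}
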