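# PSM table I/O. Schema (tab-separated, header required, UTF-8, '.' decimal):
#   spectrum_id   experiment_id   group   fraction   peptide   mods
#   charge        exp_mz          score   proteins
# 'proteins' holds semicolon-separated accessions; 'mods' holds
# comma-separated "pos:name" entries or is empty.

PSM_COLUMNS <- c("spectrum_id", "experiment_id", "group", "fraction",
                 "peptide", "mods", "charge", "exp_mz", "score", "proteins")

#' Read a PSM table
#'
#' Reads a tab-separated table of scored peptide-spectrum matches (one row
#' per PSM) and validates it. The decoy status of each PSM is derived from
#' its accessions: a PSM is a decoy match iff every mapped accession carries
#' the `REV_` prefix.
#'
#' @param path Path to a TSV file with the columns `spectrum_id`,
#'   `experiment_id`, `group` (`HC` or `NSC`), `fraction`, `peptide`,
#'   `mods`, `charge`, `exp_mz`, `score`, `proteins`.
#' @return A validated PSM data frame with an added logical `is_decoy`
#'   column.
#' @export
read_psms <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(mods = "character",
                                         proteins = "character",
                                         spectrum_id = "character"))
  validate_psms(df)
}

#' Write a PSM table
#'
#' @param psms PSM data frame (the derived `is_decoy` column is dropped).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_psms <- function(psms, path) {
  utils::write.table(psms[, PSM_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a PSM data frame
#'
#' Checks the schema, coerces types, and (re)derives the `is_decoy` flag
#' from the accession list.
#'
#' @param df Data frame of PSMs.
#' @return The validated data frame with `is_decoy` set.
#' @export
validate_psms <- function(df) {
  missing_cols <- setdiff(PSM_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("PSM table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) {
    df$is_decoy <- logical(0)
    return(df)
  }
  if (!all(df$group %in% c("HC", "NSC"))) {
    stop("PSM group must be 'HC' or 'NSC'")
  }
  df$experiment_id <- as.integer(df$experiment_id)
  df$fraction <- as.integer(df$fraction)
  df$charge <- as.integer(df$charge)
  df$score <- as.numeric(df$score)
  df$mods[is.na(df$mods)] <- ""
  if (any(!nzchar(df$proteins))) stop("every PSM must map to >= 1 protein")
  if (any(!is.finite(df$score))) stop("non-finite PSM score")
  acc <- strsplit(df$proteins, ";", fixed = TRUE)
  df$is_decoy <- vapply(acc, function(a) all(is_decoy_accession(a)), logical(1))
  df
}

# Long (PSM row, accession) pairs for protein-level grouping.
psm_protein_pairs <- function(psms) {
  acc <- strsplit(psms$proteins, ";", fixed = TRUE)
  data.frame(
    row = rep.int(seq_len(nrow(psms)), lengths(acc)),
    accession = unlist(acc, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

# Peptide identity key: sequence + modification set (charge-agnostic).
peptide_key <- function(psms) {
  mods <- psms$mods
  # normalise mod order so "3:oxidation,5:phospho" == "5:phospho,3:oxidation"
  needs <- grepl(",", mods, fixed = TRUE)
  if (any(needs)) {
    mods[needs] <- vapply(strsplit(mods[needs], ",", fixed = TRUE),
                          function(m) paste(sort(m), collapse = ","),
                          character(1))
  }
  paste0(psms$peptide, "|", mods)
}
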