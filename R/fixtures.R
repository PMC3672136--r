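# Packaged transcriptions of the source study's printed result tables:
# population-exclusive proteins (with experiments-observed and summed
# spectral counts) and Fisher-reassigned enriched proteins (with counts in
# both populations and the printed two-sided p-value).

#' Load the packaged printed-table fixtures
#'
#' Four tables transcribed from the source study: proteins exclusively
#' identified in hair cells (64 rows) and in non-sensory cells (103 rows),
#' and proteins reassigned by Fisher's exact test as enriched in hair
#' cells (53 rows) or in non-sensory cells (68 rows). One row in each
#' exclusive table could not be recovered from the available text of the
#' source and is replaced by a placeholder flagged in the `synthetic`
#' column; one hair-cell-exclusive protein (INPP5F) is printed without a
#' spectral count, transcribed as `NA`. Printed p-values are parsed to
#' numeric in `p_value` (the extreme otoferlin value is printed as 0,
#' i.e. below representable precision) with the printed text kept in
#' `p_printed`.
#'
#' @return A list of data frames: `hc_exclusive`, `nsc_exclusive`,
#'   `hc_enriched`, `nsc_enriched`.
#' @examples
#' tabs <- published_tables()
#' nrow(tabs$hc_exclusive)   # 64
#' tabs$hc_enriched[1, ]     # otoferlin, 321 vs 17 counts
#' @export
published_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "specsort",
                                  mustWork = TRUE)
  rd <- function(f) utils::read.delim(path(f), stringsAsFactors = FALSE,
                                      na.strings = "")
  hc_ex <- rd("hc_exclusive.tsv")
  nsc_ex <- rd("nsc_exclusive.tsv")
  hc_en <- rd("hc_enriched.tsv")
  nsc_en <- rd("nsc_enriched.tsv")
  for (nm in c("hc_en", "nsc_en")) {
    t <- get(nm)
    t$p_printed <- as.character(t$p_value)
    t$p_value <- as.numeric(t$p_printed)
    assign(nm, t)
  }
  list(hc_exclusive = hc_ex, nsc_exclusive = nsc_ex,
       hc_enriched = hc_en, nsc_enriched = nsc_en)
}

#' Build a count profile from the printed-table fixtures
#'
#' Rearranges the four printed tables into the `count_profile` shape that
#' [classify_exclusive()] and downstream stages consume. Exclusive-table
#' rows contribute counts to one population only; enriched-table rows
#' carry counts in both. The printed tables split experiments-observed
#' differently (out of 3 per population for exclusive rows, out of 6 total
#' for enriched rows), so `obs_total` is filled for all rows while the
#' per-population splits of enriched rows are `NA`.
#'
#' @param tables Output of [published_tables()].
#' @return A `count_profile` data frame covering the 288 printed proteins,
#'   with the printed p-values retained in the `p_printed` attribute.
#' @export
fixture_profiles <- function(tables = published_tables()) {
  ex_hc <- tables$hc_exclusive
  ex_nsc <- tables$nsc_exclusive
  en <- rbind(tables$hc_enriched[, c("description", "accession",
                                     "experiments_observed",
                                     "count_HC", "count_NSC")],
              tables$nsc_enriched[, c("description", "accession",
                                      "experiments_observed",
                                      "count_HC", "count_NSC")])
  out <- rbind(
    data.frame(accession = ex_hc$accession, description = ex_hc$description,
               count_HC = ex_hc$sum_count, count_NSC = 0L,
               obs_HC = ex_hc$experiments_observed, obs_NSC = 0L,
               obs_total = ex_hc$experiments_observed,
               stringsAsFactors = FALSE),
    data.frame(accession = ex_nsc$accession, description = ex_nsc$description,
               count_HC = 0L, count_NSC = ex_nsc$sum_count,
               obs_HC = 0L, obs_NSC = ex_nsc$experiments_observed,
               obs_total = ex_nsc$experiments_observed,
               stringsAsFactors = FALSE),
    data.frame(accession = en$accession, description = en$description,
               count_HC = en$count_HC, count_NSC = en$count_NSC,
               obs_HC = NA_integer_, obs_NSC = NA_integer_,
               obs_total = en$experiments_observed,
               stringsAsFactors = FALSE)
  )
  out$n_peptides <- NA_integer_
  rownames(out) <- NULL
  structure(out,
            p_printed = stats::setNames(
              c(tables$hc_enriched$p_value, tables$nsc_enriched$p_value),
              en$accession),
            class = c("count_profile", "data.frame"))
}

#' Filter printed p-value columns at a significance cutoff
#'
#' The printed tables round p-values to two significant digits, so a value
#' listed under a strict `p < alpha` rule can print as exactly `alpha`
#' (e.g. 0.0496 prints as 0.05). Filtering transcribed columns therefore
#' compares with `<= alpha`; recomputed p-values (see [reassign_shared()])
#' use the strict rule.
#'
#' @param table An enriched-protein fixture table with a numeric
#'   `p_value` column.
#' @param alpha Cutoff (default 0.05).
#' @return The rows whose printed p-value passes the cutoff.
#' @export
filter_printed_pvalues <- function(table, alpha = 0.05) {
  table[!is.na(table$p_value) & table$p_value <= alpha, , drop = FALSE]
}
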