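#' Per-protein spectral counts split by population
#'
#' Spectral counting sums, per protein, the number of retained PSMs as a
#' semi-quantitative abundance proxy. Each PSM contributes one count to
#' every protein it maps to (shared peptides multi-count, which biases
#' shared proteins upward; see the package vignette). Counts are
#' partitioned by population (`HC` / `NSC`) and by experiment, and the
#' number of experiments in which each protein was observed is tallied.
#'
#' @param filtered A `filtered_set` from [apply_filter_policy()], or a
#'   decoy-free PSM data frame that already passed filtering.
#' @param descriptions Optional named character vector
#'   (accession -> description) merged into the output.
#' @param normalize Optional per-protein normalization hook: a function
#'   `f(counts, accession)` applied to the final count columns. Off by
#'   default; raw summed counts are reported, as in the source analysis.
#' @return A `count_profile` data frame with one row per protein:
#'   `accession`, `description`, `count_HC`, `count_NSC`, `obs_HC`,
#'   `obs_NSC`, `obs_total` and `n_peptides`. The long per-experiment
#'   breakdown is kept in the `per_experiment` attribute.
#' @examples
#' psms <- data.frame(
#'   spectrum_id = as.character(1:3), experiment_id = c(1, 1, 2),
#'   group = "HC", fraction = 1, peptide = c("PEPTIDEK", "PEPTIDEK", "ELVISK"),
#'   mods = "", charge = 2, exp_mz = 0, score = 5, proteins = "P1"
#' )
#' count_spectra(psms)
#' @export
count_spectra <- function(filtered, descriptions = NULL, normalize = NULL) {
  retained_acc <- NULL
  if (inherits(filtered, "filtered_set")) {
    retained_acc <- filtered$proteins$accession
    psms <- filtered$psms
  } else {
    psms <- validate_psms(filtered)
    if (any(psms$is_decoy)) stop("decoy PSMs must be removed before counting")
  }
  empty <- data.frame(
    accession = character(0), description = character(0),
    count_HC = integer(0), count_NSC = integer(0),
    obs_HC = integer(0), obs_NSC = integer(0), obs_total = integer(0),
    n_peptides = integer(0), stringsAsFactors = FALSE
  )
  if (nrow(psms) == 0) return(structure(empty, class = c("count_profile", "data.frame")))

  pairs <- psm_protein_pairs(psms)
  if (!is.null(retained_acc)) {
    orphan <- !(pairs$accession %in% retained_acc)
    if (any(orphan)) {
      warning(sum(orphan), " PSM-protein link(s) reference non-retained ",
              "proteins; ignored")
      pairs <- pairs[!orphan, , drop = FALSE]
    }
  }
  pairs$group <- psms$group[pairs$row]
  pairs$experiment_id <- psms$experiment_id[pairs$row]
  pairs$pepkey <- peptide_key(psms)[pairs$row]

  per_exp <- stats::aggregate(
    list(count = rep.int(1L, nrow(pairs))),
    by = list(accession = pairs$accession, group = pairs$group,
              experiment_id = pairs$experiment_id),
    FUN = sum
  )
  accs <- sort(unique(pairs$accession))
  sum_by <- function(g) {
    sub <- per_exp[per_exp$group == g, , drop = FALSE]
    cnt <- tapply(sub$count, sub$accession, sum)
    obs <- tapply(sub$count >= 1, sub$accession, sum)
    list(count = as.integer(cnt[accs]), obs = as.integer(obs[accs]))
  }
  hc <- sum_by("HC"); nsc <- sum_by("NSC")
  npep <- tapply(pairs$pepkey, pairs$accession, function(x) length(unique(x)))
  out <- data.frame(
    accession = accs,
    description = if (is.null(descriptions)) "" else {
      d <- descriptions[accs]; d[is.na(d)] <- ""; unname(d)
    },
    count_HC = ifelse(is.na(hc$count), 0L, hc$count),
    count_NSC = ifelse(is.na(nsc$count), 0L, nsc$count),
    obs_HC = ifelse(is.na(hc$obs), 0L, hc$obs),
    obs_NSC = ifelse(is.na(nsc$obs), 0L, nsc$obs),
    stringsAsFactors = FALSE
  )
  out$obs_total <- out$obs_HC + out$obs_NSC
  out$n_peptides <- as.integer(npep[accs])
  if (!is.null(normalize)) {
    out$count_HC <- normalize(out$count_HC, out$accession)
    out$count_NSC <- normalize(out$count_NSC, out$accession)
  }
  rownames(out) <- NULL
  structure(out, per_experiment = per_exp,
            class = c("count_profile", "data.frame"))
}

#' Write a count profile as a publication-style TSV
#'
#' @param profiles A `count_profile` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_profile <- function(profiles, path) {
  cols <- c("accession", "description", "obs_HC", "obs_NSC",
            "count_HC", "count_NSC")
  utils::write.table(as.data.frame(profiles)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
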