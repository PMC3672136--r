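#' Filtering policy for the PSM -> peptide -> protein cascade
#'
#' @param psm_fdr_max,peptide_fdr_max,protein_fdr_max Maximum estimated FDR
#'   at each level, as fractions in `[0, 1]`. The study design targets a
#'   protein FDR below 3% and a peptide FDR below 1%.
#' @param min_peptides_per_protein Minimum number of distinct peptides
#'   required to report a protein (the "two peptide" rule guards against
#'   one-hit wonders in low-input samples).
#' @param estimator FDR estimator for the concatenated target-decoy search:
#'   `"concatenated"` is `2D / (T + D)`; `"ratio"` is `D / T`.
#' @return A `filter_policy` object.
#' @examples
#' filter_policy()  # the study's settings
#' @export
filter_policy <- function(psm_fdr_max = 0.05, peptide_fdr_max = 0.01,
                          protein_fdr_max = 0.03,
                          min_peptides_per_protein = 2L,
                          estimator = c("concatenated", "ratio")) {
  estimator <- match.arg(estimator)
  fr <- c(psm_fdr_max, peptide_fdr_max, protein_fdr_max)
  if (any(fr < 0 | fr > 1)) stop("FDR maxima must lie in [0, 1]")
  if (min_peptides_per_protein < 1) stop("min_peptides_per_protein must be >= 1")
  structure(
    list(psm_fdr_max = psm_fdr_max, peptide_fdr_max = peptide_fdr_max,
         protein_fdr_max = protein_fdr_max,
         min_peptides_per_protein = as.integer(min_peptides_per_protein),
         estimator = estimator),
    class = "filter_policy"
  )
}

#' Estimate the FDR of a score-thresholded hit list
#'
#' For a concatenated target-decoy search with `T` target and `D` decoy
#' hits at or above the threshold, the default estimator is
#' `2D / (T + D)`: the decoys directly count `D` incorrect hits, and
#' incorrect matches land on targets and decoys in roughly equal
#' proportions, so a further `D` incorrect hits are expected among the
#' targets. Estimates are capped at 1; an empty hit list has FDR 0 by
#' convention.
#'
#' @param scores Numeric scores (higher is better).
#' @param is_decoy Logical, parallel to `scores`.
#' @param threshold Retain hits with `score >= threshold`.
#' @param estimator `"concatenated"` (`2D/(T+D)`) or `"ratio"` (`D/T`).
#' @return Estimated FDR in `[0, 1]`.
#' @examples
#' estimate_fdr(c(rep(5, 98), 5, 5), c(rep(FALSE, 98), TRUE, TRUE), 1)  # 0.04
#' @export
estimate_fdr <- function(scores, is_decoy, threshold,
                         estimator = c("concatenated", "ratio")) {
  estimator <- match.arg(estimator)
  stopifnot(length(scores) == length(is_decoy))
  keep <- scores >= threshold
  D <- sum(is_decoy[keep])
  T_ <- sum(!is_decoy[keep])
  if (T_ + D == 0) return(0)
  est <- if (estimator == "concatenated") 2 * D / (T_ + D)
         else if (T_ == 0) Inf else D / T_
  min(est, 1)
}

#' Lowest score threshold achieving a target FDR
#'
#' Scans the observed scores and returns the lowest threshold whose
#' estimated FDR is at or below `fdr_max`, i.e. the threshold retaining the
#' most hits while meeting the bound. Ties at the threshold are retained
#' (`>=` comparison).
#'
#' @inheritParams estimate_fdr
#' @param fdr_max Maximum acceptable estimated FDR.
#' @return The threshold score. If no threshold satisfies the bound the
#'   return value is `Inf` (retaining nothing) with attribute
#'   `unsatisfiable = TRUE`.
#' @export
fdr_threshold <- function(scores, is_decoy, fdr_max,
                          estimator = c("concatenated", "ratio")) {
  estimator <- match.arg(estimator)
  if (length(scores) == 0) stop("empty hit list")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  d <- is_decoy[ord]
  cumD <- cumsum(d)
  cumT <- cumsum(!d)
  # candidate thresholds: each distinct score, evaluated over {score >= s_i}
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  est <- if (estimator == "concatenated") 2 * cumD / (cumT + cumD)
         else ifelse(cumT == 0, Inf, cumD / cumT)
  est <- pmin(est, 1)
  ok <- which(last_of_tie & est <= fdr_max)
  if (length(ok) == 0) {
    return(structure(Inf, unsatisfiable = TRUE))
  }
  s[max(ok)]
}

#' Cascaded PSM / peptide / protein FDR filtering
#'
#' Applies target-decoy FDR control at three levels in sequence:
#' \enumerate{
#'   \item PSM level: score-threshold all PSMs at `psm_fdr_max`.
#'   \item Peptide level: collapse retained PSMs to unique peptides
#'     (identity = sequence + modification set, charge-agnostic), score
#'     each peptide by its best PSM, and threshold at `peptide_fdr_max`.
#'   \item Protein level: group by accession (shared peptides count toward
#'     every mapped accession), require
#'     `min_peptides_per_protein` distinct retained peptides, score each
#'     protein by its best PSM, and threshold at `protein_fdr_max`.
#' }
#' Decoy entries are used for estimation at every level and removed from
#' the final report. An unsatisfiable policy yields an empty result with
#' diagnostics rather than an error.
#'
#' @param psms Validated PSM data frame (see [validate_psms()]).
#' @param policy A [filter_policy()].
#' @return A `filtered_set` list with elements `psms` (retained target
#'   PSMs), `peptides`, `proteins`, `achieved` (estimated FDR at each
#'   level), `thresholds`, `n_input`, `policy` and `diagnostics`.
#' @export
apply_filter_policy <- function(psms, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  psms <- validate_psms(psms)
  diagnostics <- character(0)
  empty_result <- function(diag) {
    structure(list(
      psms = psms[0, ], peptides = NULL, proteins = NULL,
      achieved = c(psm = 0, peptide = 0, protein = 0),
      thresholds = c(psm = Inf, peptide = Inf, protein = Inf),
      n_input = nrow(psms), policy = policy, diagnostics = diag
    ), class = "filtered_set")
  }
  if (nrow(psms) == 0) return(empty_result("empty PSM input"))

  # deterministic ordering: score desc, then spectrum_id asc
  psms <- psms[order(-psms$score, psms$spectrum_id), , drop = FALSE]

  ## 1. PSM level
  thr_psm <- fdr_threshold(psms$score, psms$is_decoy, policy$psm_fdr_max,
                           policy$estimator)
  if (is.infinite(thr_psm)) {
    return(empty_result("PSM-level FDR bound unsatisfiable"))
  }
  keep1 <- psms$score >= thr_psm
  achieved_psm <- estimate_fdr(psms$score, psms$is_decoy, thr_psm,
                               policy$estimator)
  p1 <- psms[keep1, , drop = FALSE]

  ## 2. peptide level: best PSM per unique peptide
  key <- peptide_key(p1)
  best <- !duplicated(key)  # p1 is score-sorted, so first hit is the best
  peptides <- data.frame(
    key = key[best], peptide = p1$peptide[best], mods = p1$mods[best],
    score = p1$score[best], is_decoy = p1$is_decoy[best],
    stringsAsFactors = FALSE
  )
  thr_pep <- fdr_threshold(peptides$score, peptides$is_decoy,
                           policy$peptide_fdr_max, policy$estimator)
  if (is.infinite(thr_pep)) {
    return(empty_result("peptide-level FDR bound unsatisfiable"))
  }
  achieved_pep <- estimate_fdr(peptides$score, peptides$is_decoy, thr_pep,
                               policy$estimator)
  peptides <- peptides[peptides$score >= thr_pep, , drop = FALSE]
  p2 <- p1[key %in% peptides$key, , drop = FALSE]

  ## 3. protein level: group by accession
  pairs <- psm_protein_pairs(p2)
  pairs$score <- p2$score[pairs$row]
  pairs$pepkey <- peptide_key(p2)[pairs$row]
  agg_pep <- tapply(pairs$pepkey, pairs$accession,
                    function(x) length(unique(x)))
  agg_score <- tapply(pairs$score, pairs$accession, max)
  proteins <- data.frame(
    accession = names(agg_pep),
    n_peptides = as.integer(agg_pep),
    score = as.numeric(agg_score[names(agg_pep)]),
    is_decoy = is_decoy_accession(names(agg_pep)),
    stringsAsFactors = FALSE
  )
  proteins <- proteins[proteins$n_peptides >= policy$min_peptides_per_protein,
                       , drop = FALSE]
  if (nrow(proteins) == 0) {
    return(empty_result("no protein meets the minimum-peptide rule"))
  }
  thr_prot <- fdr_threshold(proteins$score, proteins$is_decoy,
                            policy$protein_fdr_max, policy$estimator)
  if (is.infinite(thr_prot)) {
    return(empty_result("protein-level FDR bound unsatisfiable"))
  }
  achieved_prot <- estimate_fdr(proteins$score, proteins$is_decoy, thr_prot,
                                policy$estimator)
  proteins <- proteins[proteins$score >= thr_prot, , drop = FALSE]

  ## final report: drop decoys, keep PSMs mapping to a retained target protein
  retained_acc <- proteins$accession[!proteins$is_decoy]
  keep_rows <- unique(pairs$row[pairs$accession %in% retained_acc])
  out_psms <- p2[sort(keep_rows), , drop = FALSE]
  out_psms <- out_psms[!out_psms$is_decoy, , drop = FALSE]
  proteins <- proteins[!proteins$is_decoy, , drop = FALSE]
  peptides <- peptides[peptides$key %in% peptide_key(out_psms) &
                         !peptides$is_decoy, , drop = FALSE]
  rownames(out_psms) <- rownames(proteins) <- rownames(peptides) <- NULL

  structure(list(
    psms = out_psms, peptides = peptides, proteins = proteins,
    achieved = c(psm = achieved_psm, peptide = achieved_pep,
                 protein = achieved_prot),
    thresholds = c(psm = thr_psm, peptide = thr_pep, protein = thr_prot),
    n_input = nrow(psms), policy = policy, diagnostics = diagnostics
  ), class = "filtered_set")
}

#' @export
print.filtered_set <- function(x, ...) {
  cat("Filtered PSM set\n")
  cat(sprintf("  input PSMs:     %d\n", x$n_input))
  cat(sprintf("  retained PSMs:  %d\n", nrow(x$psms)))
  cat(sprintf("  peptides:       %d\n", if (is.null(x$peptides)) 0L else nrow(x$peptides)))
  cat(sprintf("  proteins:       %d\n", if (is.null(x$proteins)) 0L else nrow(x$proteins)))
  cat(sprintf("  achieved FDR:   psm %.3f | peptide %.3f | protein %.3f\n",
              x$achieved[["psm"]], x$achieved[["peptide"]],
              x$achieved[["protein"]]))
  if (length(x$diagnostics)) cat("  note:", x$diagnostics, "\n")
  invisible(x)
}
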