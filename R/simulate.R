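#' Configuration for the synthetic PSM generator
#'
#' The defaults emulate the source study's design: two FACS-sorted
#' populations (HC and NSC), three independent runs per population, eight
#' gel fractions per run, and a contamination fraction of unlabeled hair
#' cells sorted into the NSC fraction. Designated protein classes carry the
#' ground truth that downstream classification is benchmarked against.
#'
#' @param n_proteins Number of target proteins in the synthetic database.
#' @param n_HC_specific,n_NSC_specific Proteins present in one population
#'   only (abundance zero in the other).
#' @param n_HC_enriched,n_NSC_enriched Proteins up-weighted by
#'   `enrichment_fold` in one population, present in both.
#' @param enrichment_fold Multiplicative abundance bump for enriched
#'   proteins (> 1).
#' @param psms_per_run Scored PSMs generated per LC-MS/MS run.
#' @param n_runs_per_group Independent runs (experiments) per population.
#' @param n_fractions Gel fractions per run; proteins are binned into
#'   fractions by sequence length, a molecular-weight proxy.
#' @param contamination_epsilon Fraction of NSC-run PSMs drawn from the HC
#'   abundance profile (damaged, dye-negative hair cells sorted into the
#'   NSC gate). In `[0, 1)`.
#' @param decoy_hit_rate Fraction of PSMs that are incorrect matches; an
#'   incorrect match lands uniformly on any record of the concatenated
#'   target-decoy database, so about half are decoy hits.
#' @param score_correct,score_incorrect Gaussian `c(location, scale)` for
#'   the scores of correct and incorrect matches (a stand-in for a search
#'   engine's score distribution, adequate for FDR calibration).
#' @param min_peptide_length Shortest tryptic peptide retained in the
#'   in-silico digest.
#' @param seed Integer seed. Each run uses its own stream, seeded
#'   `seed + run_index`, so per-run output is independently reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 300,
                             n_HC_specific = 20, n_NSC_specific = 20,
                             n_HC_enriched = 20, n_NSC_enriched = 20,
                             enrichment_fold = 8,
                             psms_per_run = 5000,
                             n_runs_per_group = 3,
                             n_fractions = 8,
                             contamination_epsilon = 0.05,
                             decoy_hit_rate = 0.1,
                             score_correct = c(location = 4, scale = 0.7),
                             score_incorrect = c(location = 1.5, scale = 0.7),
                             min_peptide_length = 6,
                             seed = 1) {
  n_designated <- n_HC_specific + n_NSC_specific + n_HC_enriched + n_NSC_enriched
  if (n_designated > n_proteins) {
    stop("designated class counts exceed n_proteins")
  }
  if (contamination_epsilon < 0 || contamination_epsilon >= 1) {
    stop("contamination_epsilon must lie in [0, 1)")
  }
  if (enrichment_fold <= 1) stop("enrichment_fold must be > 1")
  structure(as.list(environment()), class = "synthetic_config")
}

#' In-silico tryptic digest of a protein sequence
#'
#' Trypsin cleaves C-terminal to lysine (K) and arginine (R) except when
#' the next residue is proline. Peptides with up to `missed` missed
#' cleavages are emitted.
#'
#' @param sequence Protein sequence string.
#' @param missed Maximum missed cleavages (default 2).
#' @param min_length Minimum peptide length to retain.
#' @return Character vector of peptides (possibly empty).
#' @examples
#' tryptic_peptides("MKLVPRGSAKWDEER", missed = 0, min_length = 1)
#' @export
tryptic_peptides <- function(sequence, missed = 2, min_length = 6) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n == 0) return(character(0))
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[pmin(cut_after + 1, n)] != "P"]
  bounds <- c(0, cut_after, n)          # segment boundaries
  starts <- bounds[-length(bounds)] + 1
  ends <- bounds[-1]
  nseg <- length(starts)
  out <- character(0)
  for (m in 0:missed) {
    if (nseg - m < 1) break
    i <- seq_len(nseg - m)
    out <- c(out, substring(sequence, starts[i], ends[i + m]))
  }
  out[nchar(out) >= min_length]
}

#' Generate a ground-truth-labeled synthetic protein database
#'
#' Draws `n_proteins` random sequences (length 100-600, uniform residues),
#' assigns each protein a designated class (`HC_SPECIFIC`, `NSC_SPECIFIC`,
#' `HC_ENRICHED`, `NSC_ENRICHED` or `BALANCED`), a base abundance weight
#' (unit-rate gamma draws, i.e. a symmetric Dirichlet profile once
#' normalized) and a gel fraction (by length octile). Deterministic under
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list with `sequences` (named character vector) and `truth`
#'   (data frame: `accession`, `class`, `length`, `weight`, `fraction`).
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_proteins
  if (n == 0) {
    return(list(sequences = stats::setNames(character(0), character(0)),
                truth = data.frame(accession = character(0),
                                   class = character(0), length = integer(0),
                                   weight = numeric(0), fraction = integer(0))))
  }
  set.seed(config$seed)
  aa <- names(amino_acid_masses()$residues)
  lens <- sample(100:600, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(aa, L, replace = TRUE), collapse = "")
  }, character(1))
  acc <- sprintf("SYNP%04d", seq_len(n))
  names(seqs) <- acc
  class <- rep("BALANCED", n)
  idx <- 0
  for (cl in c("HC_SPECIFIC", "NSC_SPECIFIC", "HC_ENRICHED", "NSC_ENRICHED")) {
    k <- config[[switch(cl, HC_SPECIFIC = "n_HC_specific",
                        NSC_SPECIFIC = "n_NSC_specific",
                        HC_ENRICHED = "n_HC_enriched",
                        NSC_ENRICHED = "n_NSC_enriched")]]
    if (k > 0) class[idx + seq_len(k)] <- cl
    idx <- idx + k
  }
  weight <- stats::rgamma(n, shape = 1, rate = 1)
  fraction <- as.integer(cut(rank(lens, ties.method = "first"),
                             breaks = config$n_fractions, labels = FALSE))
  attr(seqs, "descriptions") <- stats::setNames(
    paste("synthetic protein,", tolower(class)), acc)
  list(
    sequences = seqs,
    truth = data.frame(accession = acc, class = class, length = lens,
                       weight = weight, fraction = fraction,
                       stringsAsFactors = FALSE)
  )
}

#' Precompute tryptic digests of a synthetic database
#'
#' [generate_psms()] digests every record of the concatenated target-decoy
#' database; when many PSM tables are drawn from one database (replicated
#' simulations), attaching the digests once avoids recomputing them.
#'
#' @param database Output of [generate_database()].
#' @param config The matching [synthetic_config()].
#' @return `database` with a `digests` element added.
#' @export
digest_database <- function(database, config) {
  composite <- build_decoy_database(database$sequences)
  database$digests <- lapply(composite, tryptic_peptides, missed = 2,
                             min_length = config$min_peptide_length)
  database
}

# Population abundance profiles (unnormalized weights) from ground truth.
abundance_profiles <- function(truth, fold) {
  w <- truth$weight
  hc <- ifelse(truth$class == "NSC_SPECIFIC", 0,
               ifelse(truth$class == "HC_ENRICHED", w * fold, w))
  nsc <- ifelse(truth$class == "HC_SPECIFIC", 0,
                ifelse(truth$class == "NSC_ENRICHED", w * fold, w))
  list(HC = hc, NSC = nsc)
}

#' Generate a synthetic scored PSM table
#'
#' For each run, `psms_per_run` PSMs are drawn. A PSM is an incorrect match
#' with probability `decoy_hit_rate`: it then maps uniformly to any record
#' of the concatenated target-decoy database and scores from the incorrect
#' distribution. A correct PSM maps to a target protein drawn from the
#' run's population abundance profile (NSC runs draw from an
#' epsilon-mixture of the HC and NSC profiles, modeling hair cell
#' contamination of the NSC sort) and scores from the correct
#' distribution. The matched peptide is sampled uniformly from the
#' protein's tryptic digest (up to 2 missed cleavages); proteins whose
#' digest is empty are resampled. The observed precursor m/z is the
#' theoretical value plus ~1 ppm Gaussian noise.
#'
#' @param config A [synthetic_config()].
#' @param database Output of [generate_database()].
#' @return A list with `psms` (validated PSM data frame in the standard
#'   schema, plus `is_decoy`), `psm_truth` (data frame with per-PSM
#'   `spectrum_id`, `correct` flag and source `accession`) and `truth`
#'   (the per-protein ground truth, passed through).
#' @export
generate_psms <- function(config, database) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- database$truth
  composite <- build_decoy_database(database$sequences)
  if (!is.null(database$digests)) {
    digests <- database$digests
  } else {
    digests <- lapply(composite, tryptic_peptides,
                      missed = 2, min_length = config$min_peptide_length)
  }
  pep_counts <- lengths(digests)
  usable <- which(pep_counts > 0)
  if (length(usable) == 0) stop("no protein yields a tryptic peptide")
  n_targets <- length(database$sequences)
  profiles <- abundance_profiles(truth, config$enrichment_fold)
  # fraction of a decoy record = fraction of its target (same length)
  rec_fraction <- rep(truth$fraction, 2)

  masses <- amino_acid_masses()
  runs <- expand.grid(experiment_id = seq_len(config$n_runs_per_group),
                      group = c("HC", "NSC"), stringsAsFactors = FALSE)
  out <- vector("list", nrow(runs))
  truth_out <- vector("list", nrow(runs))

  for (r in seq_len(nrow(runs))) {
    set.seed(config$seed + r)
    grp <- runs$group[r]
    exp_id <- runs$experiment_id[r]
    n <- config$psms_per_run
    incorrect <- stats::runif(n) < config$decoy_hit_rate

    # source profile per correct PSM; NSC runs are an epsilon-mixture
    use_hc <- if (grp == "HC") rep(TRUE, n)
              else stats::runif(n) < config$contamination_epsilon
    prot <- integer(n)
    for (which_hc in c(TRUE, FALSE)) {
      sel <- !incorrect & use_hc == which_hc
      if (!any(sel)) next
      w <- if (which_hc) profiles$HC else profiles$NSC
      w[pep_counts[seq_len(n_targets)] == 0] <- 0   # resample rule
      if (sum(w) == 0) stop("abundance profile has no usable protein")
      prot[sel] <- sample.int(n_targets, sum(sel), replace = TRUE, prob = w)
    }
    if (any(incorrect)) {
      # uniform over every usable record of the composite database,
      # targets and decoys alike
      prot[incorrect] <- sample(usable, sum(incorrect), replace = TRUE)
    }

    # peptide: uniform over the protein's digest
    kpep <- pep_counts[prot]
    pick <- floor(stats::runif(n) * kpep) + 1
    peptide <- vapply(seq_len(n), function(j) digests[[prot[j]]][pick[j]],
                      character(1))
    charge <- sample(c(2L, 3L), n, replace = TRUE, prob = c(0.7, 0.3))
    upep <- unique(peptide)
    neutral <- bulk_peptide_masses(upep, table = masses)[match(peptide, upep)]
    theo_mz <- (neutral + charge * masses$proton) / charge
    exp_mz <- theo_mz * (1 + stats::rnorm(n, 0, 1e-6))
    score <- ifelse(incorrect,
                    stats::rnorm(n, config$score_incorrect[["location"]],
                                 config$score_incorrect[["scale"]]),
                    stats::rnorm(n, config$score_correct[["location"]],
                                 config$score_correct[["scale"]]))
    accession <- names(composite)[prot]
    spectrum_id <- sprintf("%s%d_S%05d", grp, exp_id, seq_len(n))
    out[[r]] <- data.frame(
      spectrum_id = spectrum_id,
      experiment_id = exp_id, group = grp,
      fraction = rec_fraction[prot],
      peptide = peptide, mods = "",
      charge = charge, exp_mz = round(exp_mz, 4),
      score = round(score, 4), proteins = accession,
      stringsAsFactors = FALSE
    )
    truth_out[[r]] <- data.frame(
      spectrum_id = spectrum_id, correct = !incorrect,
      accession = accession, stringsAsFactors = FALSE
    )
  }
  psms <- validate_psms(do.call(rbind, out))
  list(psms = psms, psm_truth = do.call(rbind, truth_out), truth = truth)
}

#' Generate a full synthetic experiment, optionally writing it to disk
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory; when given, writes
#'   `composite.fasta` (target + decoy records), `psms.tsv` and
#'   `truth.tsv`.
#' @return The [generate_psms()] result, with the database under
#'   `$database`.
#' @export
simulate_experiment <- function(config = synthetic_config(), dir = NULL) {
  db <- generate_database(config)
  sim <- generate_psms(config, db)
  sim$database <- db
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_protein_fasta(build_decoy_database(db$sequences),
                        file.path(dir, "composite.fasta"))
    write_psms(sim$psms, file.path(dir, "psms.tsv"))
    utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  sim
}
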