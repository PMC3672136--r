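#' Run the full comparative spectral-counting pipeline
#'
#' Orchestrates filter -> count -> classify -> categorize over a scored
#' PSM table and writes a publication-style report bundle: the retained PSMs,
#' the per-protein count table, one TSV per protein class (HC-only,
#' NSC-only, HC-enriched, NSC-enriched), a Venn summary JSON, optional
#' category profiles, and a run log recording every stage's input/output
#' counts and thresholds. Re-running with identical inputs produces
#' byte-identical outputs (no timestamps are written).
#'
#' @param psms A PSM data frame or path to a PSM TSV (see [read_psms()]).
#' @param out_dir Output directory, created if needed. `NULL` skips all
#'   file output and returns the result bundle only.
#' @param policy A [filter_policy()].
#' @param alpha Fisher reassignment cutoff.
#' @param margins Optional `c(T_H, T_N)` count margins; default: column
#'   sums of the filtered count profile.
#' @param annotations Optional annotation table (path or data frame, see
#'   [read_annotations()]); when given, localization and function category
#'   profiles are emitted per population.
#' @param descriptions Optional accession -> description vector.
#' @param quiet Suppress the per-stage log on stderr.
#' @return A list with `filtered`, `profiles`, `classes`, `venn`,
#'   `category_profiles`, `log` and (when writing) `paths`.
#' @export
run_pipeline <- function(psms, out_dir = NULL, policy = filter_policy(),
                         alpha = 0.05, margins = NULL, annotations = NULL,
                         descriptions = NULL, quiet = FALSE) {
  log_lines <- character(0)
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  if (is.character(psms)) psms <- read_psms(psms)
  psms <- validate_psms(psms)
  say("input", "%d PSMs, %d decoy matches", nrow(psms), sum(psms$is_decoy))

  filtered <- apply_filter_policy(psms, policy)
  say("filter",
      "retained %d PSMs, %d peptides, %d proteins (FDR psm=%.3f pep=%.3f prot=%.3f)",
      nrow(filtered$psms),
      if (is.null(filtered$peptides)) 0L else nrow(filtered$peptides),
      if (is.null(filtered$proteins)) 0L else nrow(filtered$proteins),
      filtered$achieved[["psm"]], filtered$achieved[["peptide"]],
      filtered$achieved[["protein"]])
  if (length(filtered$diagnostics)) {
    say("filter", "note: %s", paste(filtered$diagnostics, collapse = "; "))
  }

  profiles <- count_spectra(filtered, descriptions = descriptions)
  say("count", "%d protein profiles; total counts HC=%d NSC=%d",
      nrow(profiles), sum(profiles$count_HC), sum(profiles$count_NSC))

  empty_cls <- data.frame(accession = character(0), count_HC = integer(0),
                          count_NSC = integer(0), p_value = numeric(0),
                          p_adjust = numeric(0), category = character(0),
                          direction = character(0))
  if (nrow(profiles) > 0) {
    classes <- classify_proteins(profiles, margins = margins, alpha = alpha)
    venn <- attr(classes, "venn")
  } else {
    say("classify", "empty profile set; emitting empty report")
    classes <- empty_cls
    venn <- list(n_HC_only = 0L, n_NSC_only = 0L, n_shared = 0L, n_total = 0L)
  }
  say("classify",
      "HC_only=%d NSC_only=%d shared=%d (of %d); enriched HC=%d NSC=%d at alpha=%g",
      venn$n_HC_only, venn$n_NSC_only, venn$n_shared, venn$n_total,
      sum(classes$category == "HC_ENRICHED"),
      sum(classes$category == "NSC_ENRICHED"), alpha)

  category_profiles <- NULL
  if (!is.null(annotations) && nrow(profiles) > 0) {
    if (is.character(annotations)) annotations <- read_annotations(annotations)
    category_profiles <- list()
    for (axis in c("localization", "function")) {
      for (pop in c("HC", "NSC")) {
        category_profiles[[paste(axis, pop, sep = "_")]] <-
          profile_categories(profiles, annotations, axis = axis,
                             population = pop)
      }
    }
    say("categorize", "profiled %d proteins on 2 axes x 2 populations",
        nrow(profiles))
  }

  result <- list(filtered = filtered, profiles = profiles, classes = classes,
                 venn = venn, category_profiles = category_profiles,
                 alpha = alpha, log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      psms = file.path(out_dir, "filtered_psms.tsv"),
      counts = file.path(out_dir, "counts.tsv"),
      venn = file.path(out_dir, "venn.json"),
      log = file.path(out_dir, "run.log")
    )
    write_psms(filtered$psms, paths[["psms"]])
    write_count_profile(profiles, paths[["counts"]])
    jsonlite::write_json(venn, paths[["venn"]], auto_unbox = TRUE)
    for (cls in c("HC_ONLY", "NSC_ONLY", "HC_ENRICHED", "NSC_ENRICHED")) {
      sub <- classes[classes$category == cls, , drop = FALSE]
      # rank by abundance in the class's own population, like the tables
      own <- if (startsWith(cls, "HC")) sub$count_HC else sub$count_NSC
      sub <- sub[order(-ifelse(is.na(own), 0, own), sub$accession),
                 , drop = FALSE]
      sub$p_value <- format_pvalue(sub$p_value)
      f <- file.path(out_dir, paste0(tolower(cls), ".tsv"))
      utils::write.table(
        sub[, c("accession", "count_HC", "count_NSC", "p_value")],
        f, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
      paths[[tolower(cls)]] <- f
    }
    if (!is.null(category_profiles)) {
      for (nm in names(category_profiles)) {
        f <- file.path(out_dir, paste0("categories_", nm, ".tsv"))
        utils::write.table(as.data.frame(category_profiles[[nm]]), f,
                           sep = "\t", quote = FALSE, row.names = FALSE)
        paths[[paste0("categories_", nm)]] <- f
      }
    }
    writeLines(log_lines, paths[["log"]])
    result$paths <- paths
  }
  result
}

#' Run the pipeline from a JSON configuration
#'
#' The configuration document has keys `psms` (path), optional
#' `annotations` (path), optional `database` (FASTA path, used for
#' protein descriptions), `out_dir`, optional `policy` (object with
#' `psm_fdr_max`, `peptide_fdr_max`, `protein_fdr_max`,
#' `min_peptides_per_protein`, `estimator`), optional `alpha`, optional
#' `margins`. A `simulate` object (fields of [synthetic_config()])
#' replaces `psms` with a generated experiment; its `seed` governs all
#' randomness.
#'
#' @param config Path to a JSON file, or an equivalent named list.
#' @param overrides Named list overriding top-level config keys (the CLI
#'   maps flags here).
#' @return The [run_pipeline()] result.
#' @export
run_pipeline_config <- function(config, overrides = list()) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  config[names(overrides)] <- overrides
  policy <- do.call(filter_policy, as.list(config$policy))
  descriptions <- NULL
  if (!is.null(config$simulate)) {
    sim_cfg <- do.call(synthetic_config, as.list(config$simulate))
    sim <- simulate_experiment(sim_cfg)
    psms <- sim$psms
    descriptions <- attr(sim$database$sequences, "descriptions")
  } else {
    if (is.null(config$psms)) stop("config needs 'psms' or 'simulate'")
    psms <- config$psms
    if (!is.null(config$database)) {
      db <- read_protein_fasta(config$database)
      descriptions <- attr(db, "descriptions")
    }
  }
  run_pipeline(psms,
               out_dir = config$out_dir,
               policy = policy,
               alpha = if (is.null(config$alpha)) 0.05 else config$alpha,
               margins = config$margins,
               annotations = config$annotations,
               descriptions = descriptions)
}

#' Human-readable summary of a pipeline result
#'
#' @param result A [run_pipeline()] result bundle.
#' @param top_n Number of top enriched proteins (by summed count) listed
#'   per direction.
#' @param path Optional file to write the markdown report to.
#' @return Character vector of markdown lines, invisibly when writing.
#' @export
make_report <- function(result, top_n = 10, path = NULL) {
  f <- result$filtered
  lines <- c(
    "# Pipeline report", "",
    "## Filtering", "",
    "| stage | retained | achieved FDR | threshold |",
    "|---|---|---|---|",
    sprintf("| PSM | %d | %.4f | %s |", nrow(f$psms),
            f$achieved[["psm"]], format(f$thresholds[["psm"]])),
    sprintf("| peptide | %d | %.4f | %s |",
            if (is.null(f$peptides)) 0L else nrow(f$peptides),
            f$achieved[["peptide"]], format(f$thresholds[["peptide"]])),
    sprintf("| protein | %d | %.4f | %s |",
            if (is.null(f$proteins)) 0L else nrow(f$proteins),
            f$achieved[["protein"]], format(f$thresholds[["protein"]])),
    "",
    "## Venn", "",
    sprintf("HC only: %d | NSC only: %d | shared: %d | total: %d",
            result$venn$n_HC_only, result$venn$n_NSC_only,
            result$venn$n_shared, result$venn$n_total),
    ""
  )
  for (dirn in c("HC_ENRICHED", "NSC_ENRICHED")) {
    sub <- result$classes[result$classes$category == dirn, , drop = FALSE]
    lines <- c(lines, sprintf("## Top %s (by count in its population)", dirn),
               "")
    if (nrow(sub) == 0) {
      lines <- c(lines, "(none)", "")
      next
    }
    own <- if (dirn == "HC_ENRICHED") sub$count_HC else sub$count_NSC
    sub <- sub[order(-own), , drop = FALSE]
    sub <- utils::head(sub, top_n)
    lines <- c(lines,
               "| accession | count HC | count NSC | p |", "|---|---|---|---|",
               sprintf("| %s | %d | %d | %s |", sub$accession, sub$count_HC,
                       sub$count_NSC, format_pvalue(sub$p_value)),
               "")
  }
  missing <- setdiff(c("filtered", "profiles", "classes", "venn"),
                     names(Filter(Negate(is.null), result)))
  if (length(missing)) {
    lines <- c(lines, "## Missing stage outputs", "", paste("-", missing), "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
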