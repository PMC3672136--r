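#' Default category vocabularies for protein annotation
#'
#' Vocabulary for the two annotation axes: subcellular localization and
#' predicted cellular function. Both end in `"not annotated"`, the bucket
#' for accessions missing from the annotation table. The localization list
#' mirrors the compartments of a typical secretory/endocytic cell; the
#' function list mirrors broad gene-ontology-style process groups.
#'
#' @return Named list with character vectors `localization` and `function_`.
#' @export
category_vocabularies <- function() {
  list(
    localization = c("cytoplasm", "nucleus", "mitochondrion", "vesicle",
                     "plasma membrane", "ER", "Golgi", "lysosome",
                     "secreted", "cytoskeleton", "not annotated"),
    function_ = c("energy metabolism", "trafficking", "signal transduction",
                  "protein synthesis", "protein degradation",
                  "protein folding", "cytoskeleton", "transcription",
                  "extracellular matrix", "other", "not annotated")
  )
}

#' Read an accession-to-category annotation table
#'
#' Annotations are a user-supplied snapshot (TSV with header: `accession`,
#' `localization`, `function`), never a live ontology query, so analyses
#' are reproducible against a fixed annotation state. A protein with
#' multiple listed categories (semicolon-separated) keeps the first.
#'
#' @param path Path to the TSV file.
#' @param vocab Category vocabularies, see [category_vocabularies()];
#'   values outside the vocabulary raise an error.
#' @return An `annotation_map` data frame.
#' @export
read_annotations <- function(path, vocab = category_vocabularies()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "function."] <- "function"  # read.delim mangling
  required <- c("accession", "localization", "function")
  if (!all(required %in% names(df))) {
    stop("annotation table must have columns: ",
         paste(required, collapse = ", "))
  }
  df$localization <- sub(";.*$", "", df$localization)
  df[["function"]] <- sub(";.*$", "", df[["function"]])
  bad_loc <- setdiff(unique(df$localization), vocab$localization)
  bad_fun <- setdiff(unique(df[["function"]]), vocab$function_)
  if (length(bad_loc) || length(bad_fun)) {
    stop("annotation categories outside the vocabulary: ",
         paste(c(bad_loc, bad_fun), collapse = ", "))
  }
  structure(df[, required], vocab = vocab,
            class = c("annotation_map", "data.frame"))
}

# Resolve each accession to its category on one axis ("not annotated" when
# unmapped).
resolve_categories <- function(accessions, annot, axis) {
  col <- if (axis == "localization") "localization" else "function"
  idx <- match(accessions, annot$accession)
  cat <- annot[[col]][idx]
  cat[is.na(cat)] <- "not annotated"
  cat
}

#' Category proportions of a protein set, before and after quantification
#'
#' "Before quantification" weights every protein equally (the proportion of
#' proteins per category); "after quantification" weights by spectral
#' counts (the proportion of total counts per category), which shifts the
#' profile toward categories holding abundant proteins.
#'
#' @param profiles A `count_profile` data frame, or any data frame with
#'   `accession`, `count_HC`, `count_NSC`.
#' @param annot An `annotation_map` from [read_annotations()], or a data
#'   frame with `accession`, `localization`, `function` columns.
#' @param axis `"localization"` or `"function"`.
#' @param population `"HC"`, `"NSC"` or `"both"`: which population's counts
#'   feed the after-quantification weighting.
#' @param vocab Category vocabulary for the axis (ordered output rows).
#' @return A `category_profile` data frame: `category`, `n_proteins`,
#'   `n_counts`, `proportion_before`, `proportion_after`. Each proportion
#'   column sums to 1.
#' @export
profile_categories <- function(profiles, annot,
                               axis = c("localization", "function"),
                               population = c("both", "HC", "NSC"),
                               vocab = NULL) {
  axis <- match.arg(axis)
  population <- match.arg(population)
  if (nrow(profiles) == 0) stop("empty protein list")
  if (is.null(vocab)) {
    v <- attr(annot, "vocab")
    if (is.null(v)) v <- category_vocabularies()
    vocab <- if (axis == "localization") v$localization else v$function_
  }
  if (length(vocab) == 0) stop("empty category vocabulary")
  cat <- resolve_categories(profiles$accession, annot, axis)
  extra <- setdiff(unique(cat), vocab)
  if (length(extra)) stop("categories outside the vocabulary: ",
                          paste(extra, collapse = ", "))
  counts <- switch(population,
    both = rowSums(cbind(profiles$count_HC, profiles$count_NSC), na.rm = TRUE),
    HC = ifelse(is.na(profiles$count_HC), 0, profiles$count_HC),
    NSC = ifelse(is.na(profiles$count_NSC), 0, profiles$count_NSC)
  )
  cat <- factor(cat, levels = vocab)
  n_prot <- as.integer(table(cat))
  n_cnt <- as.numeric(tapply(counts, cat, sum, default = 0))
  out <- data.frame(
    category = vocab,
    n_proteins = n_prot,
    n_counts = n_cnt,
    proportion_before = n_prot / sum(n_prot),
    proportion_after = if (sum(n_cnt) > 0) n_cnt / sum(n_cnt) else
      rep(NA_real_, length(vocab)),
    stringsAsFactors = FALSE
  )
  structure(out, axis = axis, population = population,
            class = c("category_profile", "data.frame"))
}

#' Difference between two category profiles, in percentage points
#'
#' @param profile_HC,profile_NSC Two `category_profile` data frames over
#'   the same vocabulary (e.g. the HC and NSC population profiles).
#' @return Data frame with `category`, `diff_before_pp` and
#'   `diff_after_pp`: signed differences `(HC - NSC) * 100`. Each
#'   difference column sums to 0.
#' @export
compare_profiles <- function(profile_HC, profile_NSC) {
  if (!identical(profile_HC$category, profile_NSC$category)) {
    stop("profiles must share the same category vocabulary, in order")
  }
  data.frame(
    category = profile_HC$category,
    diff_before_pp = 100 * (profile_HC$proportion_before -
                              profile_NSC$proportion_before),
    diff_after_pp = 100 * (profile_HC$proportion_after -
                             profile_NSC$proportion_after),
    stringsAsFactors = FALSE
  )
}
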