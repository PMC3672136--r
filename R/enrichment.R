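#' Two-sided Fisher's exact test for a 2x2 contingency table
#'
#' Computes the exact two-sided p-value for a table
#' `[a, b; c, d]` whose columns are the two populations (HC, NSC): `a` and
#' `b` are the protein's spectral counts, `c = T_H - a` and `d = T_N - b`
#' the remaining count margins. Conditional on the margins, `a` follows a
#' hypergeometric distribution; the default two-sided rule
#' (`method = "minlike"`) sums the probabilities of every table whose point
#' probability does not exceed that of the observed table (within relative
#' tolerance 1e-7, the convention of `stats::fisher.test`). The alternative
#' `method = "double"` doubles the smaller one-sided tail and caps at 1.
#'
#' @param a,b,c,d Non-negative cell counts, or `a` may be a 2x2 matrix /
#'   length-4 vector `(a, b, c, d)`.
#' @param method Two-sided rule: `"minlike"` (default) or `"double"`.
#' @return Exact p-value in `(0, 1]`.
#' @examples
#' fisher_exact_two_sided(5, 5, 95, 95)   # 1
#' fisher_exact_two_sided(3, 0, 0, 3)     # 0.1
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL,
                                   method = c("minlike", "double")) {
  method <- match.arg(method)
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  } else if (is.null(b) && length(a) == 4) {
    b <- a[2]; c <- a[3]; d <- a[4]; a <- a[1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("contingency cells must be non-negative")
  if (any(cells != round(cells))) stop("contingency cells must be integers")
  T_H <- a + c   # column margin, population 1
  T_N <- b + d   # column margin, population 2
  m <- a + b     # row margin: this protein's total count
  if (m == 0 || T_H + T_N == 0) return(1)
  support <- max(0, m - T_N):min(m, T_H)
  probs <- stats::dhyper(support, T_H, T_N, m)
  p_obs <- probs[match(a, support)]
  if (method == "minlike") {
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(probs[support <= a])
    upper <- sum(probs[support >= a])
    p <- min(1, 2 * min(lower, upper))
  }
  min(max(p, p_obs), 1)
}

#' Partition proteins into population-exclusive and shared sets
#'
#' A protein is HC-exclusive if it has spectral counts in the hair cell
#' population only, NSC-exclusive if counted in the non-sensory population
#' only, and shared otherwise. A recorded detection with a missing count
#' (a transcription gap in a printed table) is treated as present.
#'
#' @param profiles A `count_profile` data frame (see [count_spectra()]).
#' @return A list with `categories` (data frame: `accession`, `category`
#'   in `HC_ONLY` / `NSC_ONLY` / `SHARED`) and `venn` (list with
#'   `n_HC_only`, `n_NSC_only`, `n_shared`, `n_total`).
#' @export
classify_exclusive <- function(profiles) {
  present_HC <- ifelse(is.na(profiles$count_HC),
                       profiles$obs_HC > 0, profiles$count_HC > 0)
  present_NSC <- ifelse(is.na(profiles$count_NSC),
                        profiles$obs_NSC > 0, profiles$count_NSC > 0)
  if (any(!present_HC & !present_NSC)) {
    stop("profile(s) with zero counts in both populations cannot have ",
         "passed upstream filtering: ",
         paste(utils::head(profiles$accession[!present_HC & !present_NSC], 5),
               collapse = ", "))
  }
  category <- ifelse(present_HC & !present_NSC, "HC_ONLY",
                     ifelse(!present_HC & present_NSC, "NSC_ONLY", "SHARED"))
  venn <- list(
    n_HC_only = sum(category == "HC_ONLY"),
    n_NSC_only = sum(category == "NSC_ONLY"),
    n_shared = sum(category == "SHARED"),
    n_total = length(category)
  )
  list(
    categories = data.frame(accession = profiles$accession,
                            category = category, stringsAsFactors = FALSE),
    venn = venn
  )
}

#' Number of shared proteins from Venn totals
#'
#' @param n_total Total number of identified proteins.
#' @param n_HC_only,n_NSC_only Exclusive counts per population.
#' @return `n_total - n_HC_only - n_NSC_only`.
#' @examples
#' venn_shared_count(634, 64, 103)  # 467
#' @export
venn_shared_count <- function(n_total, n_HC_only, n_NSC_only) {
  shared <- n_total - n_HC_only - n_NSC_only
  if (shared < 0) stop("exclusive counts exceed the total")
  shared
}

#' Reassign shared proteins by Fisher's exact test
#'
#' Cross-contamination between sorted populations (e.g. damaged, unlabeled
#' hair cells sorted into the non-sensory fraction) can mask genuinely
#' population-specific proteins as shared. For each shared protein this
#' builds the 2x2 table of its counts against the remaining count margins,
#' computes the two-sided Fisher p-value, and — when `p < alpha` — assigns
#' the protein to the population with the higher count rate.
#'
#' @param profiles A `count_profile` data frame.
#' @param margins Numeric length-2 vector `c(T_H, T_N)`: total retained
#'   spectral counts per population over the whole filtered protein set.
#'   Defaults to the column sums of `profiles` (missing counts excluded).
#' @param alpha Significance cutoff; the source analysis uses 0.05,
#'   uncorrected.
#' @param method Two-sided rule, see [fisher_exact_two_sided()].
#' @return A data frame with one row per shared protein: `accession`,
#'   `count_HC`, `count_NSC`, `p_value`, `p_adjust` (Benjamini-Hochberg,
#'   informational only), `category` (`HC_ENRICHED`, `NSC_ENRICHED` or
#'   `SHARED_UNRESOLVED`) and `direction` (`HC`, `NSC` or `none`).
#' @export
reassign_shared <- function(profiles, margins = NULL, alpha = 0.05,
                            method = c("minlike", "double")) {
  method <- match.arg(method)
  cls <- classify_exclusive(profiles)
  shared <- profiles[cls$categories$category == "SHARED", , drop = FALSE]
  if (is.null(margins)) {
    margins <- c(sum(profiles$count_HC, na.rm = TRUE),
                 sum(profiles$count_NSC, na.rm = TRUE))
  }
  T_H <- margins[1]; T_N <- margins[2]
  if (nrow(shared) > 0 &&
      (any(shared$count_HC > T_H) || any(shared$count_NSC > T_N))) {
    stop("margins smaller than a per-protein count")
  }
  n <- nrow(shared)
  p <- numeric(n); direction <- character(n)
  for (i in seq_len(n)) {
    a <- shared$count_HC[i]; b <- shared$count_NSC[i]
    p[i] <- fisher_exact_two_sided(a, b, T_H - a, T_N - b, method = method)
    rate_H <- a / T_H; rate_N <- b / T_N
    direction[i] <- if (rate_H > rate_N) "HC"
                    else if (rate_N > rate_H) "NSC" else "none"
  }
  significant <- p < alpha & direction != "none"
  category <- ifelse(significant & direction == "HC", "HC_ENRICHED",
                     ifelse(significant & direction == "NSC", "NSC_ENRICHED",
                            "SHARED_UNRESOLVED"))
  direction[!significant] <- "none"
  data.frame(
    accession = shared$accession,
    count_HC = shared$count_HC, count_NSC = shared$count_NSC,
    p_value = p,
    p_adjust = stats::p.adjust(p, method = "BH"),
    category = category, direction = direction,
    stringsAsFactors = FALSE
  )
}

#' Full exclusive + enrichment classification of a count profile
#'
#' Combines [classify_exclusive()] and [reassign_shared()]: proteins seen
#' in one population only are `HC_ONLY` / `NSC_ONLY`; shared proteins with
#' a significant two-sided Fisher p-value are reassigned as
#' `HC_ENRICHED` / `NSC_ENRICHED`; the rest stay `SHARED_UNRESOLVED`.
#'
#' @inheritParams reassign_shared
#' @return A data frame with `accession`, `count_HC`, `count_NSC`,
#'   `p_value` (NA for exclusives), `category` and `direction`, carrying
#'   the Venn summary in the `venn` attribute.
#' @export
classify_proteins <- function(profiles, margins = NULL, alpha = 0.05,
                              method = c("minlike", "double")) {
  cls <- classify_exclusive(profiles)
  shared_res <- reassign_shared(profiles, margins = margins, alpha = alpha,
                                method = method)
  excl <- cls$categories[cls$categories$category != "SHARED", , drop = FALSE]
  out_excl <- data.frame(
    accession = excl$accession,
    count_HC = profiles$count_HC[match(excl$accession, profiles$accession)],
    count_NSC = profiles$count_NSC[match(excl$accession, profiles$accession)],
    p_value = rep(NA_real_, nrow(excl)),
    p_adjust = rep(NA_real_, nrow(excl)),
    category = excl$category,
    direction = ifelse(excl$category == "HC_ONLY", "HC", "NSC"),
    stringsAsFactors = FALSE
  )
  out <- rbind(out_excl, shared_res)
  out <- out[match(profiles$accession, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, venn = cls$venn)
}

#' Format p-values in printed-table style
#'
#' Two significant digits, scientific notation for small values, and `"0"`
#' for values that underflow below 1e-300 (as printed for extreme count
#' asymmetries such as otoferlin's).
#'
#' @param p Numeric p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 1e-300) return("0")
    format(signif(x, 2), scientific = NA, trim = TRUE)
  }, character(1))
}
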