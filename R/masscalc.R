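#' Monoisotopic amino acid residue mass table
#'
#' Returns the monoisotopic residue masses (Da) of the 20 standard amino
#' acids together with the mass of water and of a proton. Residue masses are
#' the masses of the amino acids minus water, i.e. the mass each residue
#' contributes inside a peptide chain.
#'
#' @return A list with components `residues` (named numeric vector, one
#'   entry per single-letter residue code), `water` (Da) and `proton` (Da).
#' @examples
#' tab <- amino_acid_masses()
#' tab$residues[["G"]]  # glycine, 57.02146 Da
#' @export
amino_acid_masses <- function() {
  list(
    residues = c(
      G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
      V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
      I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
      K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
      F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
    ),
    water  = 18.0105646863,
    proton = 1.00727646688
  )
}

#' Default peptide modification registry
#'
#' The modifications used in the source study's database search: a static
#' propionamide adduct on cysteine (from acrylamide in the gel), and
#' variable methionine oxidation, lysine acetylation, serine/threonine/
#' tyrosine phosphorylation and lysine ubiquitination (the GlyGly remnant
#' left by tryptic digestion of a ubiquitin conjugate). Mass deltas are
#' monoisotopic sums of the standard elemental compositions.
#'
#' @return A data frame with columns `name`, `residues` (string of
#'   single-letter codes the modification may sit on), `delta_mass` (Da)
#'   and `mode` (`"static"` or `"variable"`).
#' @examples
#' default_modifications()
#' @export
default_modifications <- function() {
  data.frame(
    name = c("propionamide", "oxidation", "acetyl", "phospho", "glygly"),
    residues = c("C", "M", "K", "STY", "K"),
    delta_mass = c(71.037114, 15.994915, 42.010565, 79.966331, 114.042927),
    mode = c("static", "variable", "variable", "variable", "variable"),
    stringsAsFactors = FALSE
  )
}

#' Read a modification registry from TSV or JSON
#'
#' A registry file lists one modification per record with fields `name`,
#' `residues`, `delta_mass` and `mode` (see [default_modifications()] for
#' the expected shape).
#'
#' @param path Path to a tab-separated file (with header) or a `.json` file.
#' @return A modification registry data frame.
#' @export
read_modifications <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    reg <- jsonlite::fromJSON(path)
    reg <- as.data.frame(reg, stringsAsFactors = FALSE)
  } else {
    reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  required <- c("name", "residues", "delta_mass", "mode")
  if (!all(required %in% names(reg))) {
    stop("modification registry must have columns: ",
         paste(required, collapse = ", "))
  }
  if (!all(is.finite(reg$delta_mass))) stop("non-finite delta_mass in registry")
  if (!all(reg$mode %in% c("static", "variable"))) {
    stop("modification mode must be 'static' or 'variable'")
  }
  reg
}

# Parse "pos:name" strings into a data.frame(position, name); accepts an
# already-built data.frame unchanged.
parse_mods <- function(mods) {
  if (is.null(mods) || length(mods) == 0) {
    return(data.frame(position = integer(0), name = character(0)))
  }
  if (is.data.frame(mods)) {
    stopifnot(all(c("position", "name") %in% names(mods)))
    return(mods[, c("position", "name")])
  }
  parts <- strsplit(as.character(mods), ":", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("modification spec must be 'position:name', got: ",
                     paste(mods[bad], collapse = ", "))
  data.frame(
    position = as.integer(vapply(parts, `[[`, "", 1L)),
    name = vapply(parts, `[[`, "", 2L)
  )
}

# Validate a peptide's residues and modification placements against the
# registry; returns the per-position modification delta vector.
mod_deltas <- function(residues, mods, registry) {
  deltas <- numeric(length(residues))
  # static modifications apply at every occurrence of their target residues
  statics <- registry[registry$mode == "static", , drop = FALSE]
  for (i in seq_len(nrow(statics))) {
    targets <- strsplit(statics$residues[i], "")[[1]]
    hit <- residues %in% targets
    deltas[hit] <- deltas[hit] + statics$delta_mass[i]
  }
  mods <- parse_mods(mods)
  if (nrow(mods) > 0) {
    idx <- match(mods$name, registry$name)
    if (anyNA(idx)) {
      stop("unknown modification name(s): ",
           paste(unique(mods$name[is.na(idx)]), collapse = ", "))
    }
    if (any(mods$position < 1L | mods$position > length(residues))) {
      stop("modification position outside peptide")
    }
    for (j in seq_len(nrow(mods))) {
      row <- registry[idx[j], ]
      targets <- strsplit(row$residues, "")[[1]]
      if (!residues[mods$position[j]] %in% targets) {
        stop("modification '", row$name, "' at position ", mods$position[j],
             " does not target residue '", residues[mods$position[j]], "'")
      }
      if (row$mode == "variable") {
        deltas[mods$position[j]] <- deltas[mods$position[j]] + row$delta_mass
      }
      # declaring a static mod at a position is allowed but adds nothing:
      # it is already applied at every occurrence
    }
  }
  deltas
}

# Split a peptide string into validated residues.
peptide_residues <- function(sequence, table) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    stop("peptide sequence must be a single non-empty string")
  }
  residues <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(residues, names(table$residues))
  if (length(unknown) > 0) {
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
  }
  residues
}

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' The neutral mass is the sum of the residue masses plus one water
#' (the peptide's terminal H and OH), plus the mass deltas of all static
#' modifications at their target residues and of the declared variable
#' modifications.
#'
#' @param sequence Peptide as a string of single-letter residue codes.
#' @param mods Variable modifications, as `"position:name"` strings
#'   (1-based positions) or a data frame with columns `position`, `name`.
#' @param table Residue mass table, see [amino_acid_masses()].
#' @param registry Modification registry, see [default_modifications()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("ETLYGQEIDQASFLTILK")  # 2068.0728
#' peptide_mass("PEPTIDEMK", mods = "8:oxidation")
#' @export
peptide_mass <- function(sequence, mods = NULL,
                         table = amino_acid_masses(),
                         registry = default_modifications()) {
  residues <- peptide_residues(sequence, table)
  sum(table$residues[residues]) + table$water +
    sum(mod_deltas(residues, mods, registry))
}

# Residue masses with static modification deltas folded in, for bulk mass
# computation over many unmodified-variable peptides at once.
residue_mass_vector <- function(table = amino_acid_masses(),
                                registry = default_modifications()) {
  res <- table$residues
  statics <- registry[registry$mode == "static", , drop = FALSE]
  for (i in seq_len(nrow(statics))) {
    targets <- strsplit(statics$residues[i], "")[[1]]
    res[targets] <- res[targets] + statics$delta_mass[i]
  }
  res
}

# Vectorized neutral masses of peptides without variable modifications.
bulk_peptide_masses <- function(peptides, table = amino_acid_masses(),
                                registry = default_modifications()) {
  rv <- residue_mass_vector(table, registry)
  vapply(strsplit(peptides, "", fixed = TRUE),
         function(r) sum(rv[r]), numeric(1)) + table$water
}

#' Precursor m/z from neutral mass and charge
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @param table Residue mass table (supplies the proton mass).
#' @return Mass-to-charge ratio `(M + z * proton) / z`.
#' @examples
#' precursor_mz(2068.0728, 2)  # 1035.0437
#' @export
precursor_mz <- function(neutral_mass, charge, table = amino_acid_masses()) {
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer")
  }
  (neutral_mass + charge * table$proton) / charge
}

#' Signed relative mass error in parts per million
#'
#' @param experimental_mz Observed m/z.
#' @param theoretical_mz Theoretical m/z; must be positive.
#' @return `(experimental - theoretical) / theoretical * 1e6`, signed.
#' @examples
#' ppm_error(1035.0452, 1035.0437)  # +1.45 ppm
#' @export
ppm_error <- function(experimental_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) stop("theoretical m/z must be positive")
  (experimental_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' b- and y-series fragment ion m/z ladder
#'
#' Backbone cleavage between the carbonyl carbon and the amide nitrogen
#' yields b ions (N-terminal piece) and y ions (C-terminal piece). The i-th
#' b ion contains residues 1..i; the j-th y ion contains the last j residues
#' plus water. The full-length ion is excluded, so a peptide of n residues
#' yields n - 1 ions per series.
#'
#' @param sequence Peptide string.
#' @param series `"b"` or `"y"`.
#' @param frag_charge Fragment charge state (>= 1).
#' @param mods Variable modifications as in [peptide_mass()]; a
#'   modification's delta travels with the fragment that contains its
#'   residue.
#' @param table,registry Mass table and modification registry.
#' @return Numeric vector of m/z values, index i = ion number.
#' @examples
#' fragment_series("GG", "b")  # 58.0287
#' fragment_series("GG", "y")  # 76.0393
#' @export
fragment_series <- function(sequence, series = c("b", "y"), frag_charge = 1L,
                            mods = NULL,
                            table = amino_acid_masses(),
                            registry = default_modifications()) {
  series <- match.arg(series)
  if (frag_charge < 1) stop("fragment charge must be >= 1")
  residues <- peptide_residues(sequence, table)
  n <- length(residues)
  if (n < 2) return(numeric(0))
  per_res <- table$residues[residues] + mod_deltas(residues, mods, registry)
  if (series == "b") {
    neutral <- cumsum(per_res)[-n]           # residues 1..i, no water
  } else {
    neutral <- cumsum(rev(per_res))[-n] + table$water  # y_j = last j residues
  }
  unname((neutral + frag_charge * table$proton) / frag_charge)
}
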