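# Elemental monoisotopic masses, the independent oracle for residue sums.
EL <- c(H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
        S = 31.97207100, P = 30.97376163)
el_mass <- function(counts) sum(EL[names(counts)] * counts)

test_that("mass table matches elemental-composition sums", {
  tab <- amino_acid_masses()
  expect_setequal(names(tab$residues), strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]])
  expect_true(all(tab$residues > 0))
  expect_equal(tab$water, el_mass(c(H = 2, O = 1)), tolerance = 1e-9)
  expect_equal(tab$proton, 1.007276, tolerance = 5e-7)
  # spot-check residues against their compositions
  expect_equal(tab$residues[["G"]], el_mass(c(C = 2, H = 3, N = 1, O = 1)),
               tolerance = 1e-5)
  expect_equal(tab$residues[["K"]], el_mass(c(C = 6, H = 12, N = 2, O = 1)),
               tolerance = 1e-5)
  expect_equal(tab$residues[["W"]], el_mass(c(C = 11, H = 10, N = 2, O = 1)),
               tolerance = 1e-5)
})

test_that("modification deltas match their elemental compositions", {
  reg <- default_modifications()
  d <- function(nm) reg$delta_mass[reg$name == nm]
  expect_equal(d("propionamide"), el_mass(c(C = 3, H = 5, N = 1, O = 1)),
               tolerance = 1e-5)
  expect_equal(d("oxidation"), el_mass(c(O = 1)), tolerance = 1e-5)
  expect_equal(d("acetyl"), el_mass(c(C = 2, H = 2, O = 1)), tolerance = 1e-5)
  expect_equal(d("phospho"), el_mass(c(H = 1, P = 1, O = 3)), tolerance = 1e-5)
  expect_equal(d("glygly"), el_mass(c(C = 4, H = 6, N = 2, O = 2)),
               tolerance = 1e-5)
})

test_that("peptide neutral mass reproduces the otolin-1 anchor peptide", {
  m <- peptide_mass("ETLYGQEIDQASFLTILK")
  expect_equal(m, 2068.0728, tolerance = 5e-4)
  expect_equal(precursor_mz(m, 2), 1035.0437, tolerance = 5e-4)
})

test_that("single glycine and composition symmetry", {
  expect_equal(peptide_mass("G"), 75.0320, tolerance = 5e-4)
  expect_equal(peptide_mass("AG"), peptide_mass("GA"))
})

test_that("invalid peptides and modifications are rejected", {
  expect_error(peptide_mass(""), "non-empty")
  expect_error(peptide_mass("AXZ"), "unknown residue")
  expect_error(peptide_mass("PEPTIDEK", mods = "99:oxidation"), "position")
  expect_error(peptide_mass("PEPTIDEK", mods = "1:oxidation"), "target")
  expect_error(peptide_mass("PEPTIDEK", mods = "1:nosuchmod"), "unknown modification")
})

test_that("static propionamide applies to every cysteine automatically", {
  tab <- amino_acid_masses()
  reg <- default_modifications()
  delta <- reg$delta_mass[reg$name == "propionamide"]
  expect_equal(peptide_mass("GACGA") - peptide_mass("GAGA"),
               tab$residues[["C"]] + delta, tolerance = 1e-9)
  expect_equal(peptide_mass("CC"),
               2 * (tab$residues[["C"]] + delta) + tab$water,
               tolerance = 1e-9)
})

test_that("variable modification round-trip restores the original mass", {
  m0 <- peptide_mass("MSTYKEK")
  m1 <- peptide_mass("MSTYKEK", mods = c("1:oxidation", "3:phospho"))
  reg <- default_modifications()
  expect_identical(m1 - reg$delta_mass[reg$name == "oxidation"] -
                     reg$delta_mass[reg$name == "phospho"], m0)
})

test_that("precursor m/z formula and validation", {
  expect_equal(precursor_mz(1000, 1), 1000 + 1.007276, tolerance = 1e-6)
  expect_equal(precursor_mz(1000, 4), 251.007276, tolerance = 1e-6)
  expect_error(precursor_mz(1000, 0), "charge")
  expect_error(precursor_mz(1000, 1.5), "charge")
})

test_that("ppm error is signed and validated", {
  expect_equal(ppm_error(1035.0452, 1035.0437), 1.449, tolerance = 0.01)
  expect_lt(abs(ppm_error(1035.0452, 1035.0437)), 2)
  expect_identical(ppm_error(500, 500), 0)
  expect_equal(ppm_error(999.999, 1000), -1.0, tolerance = 1e-9)
  expect_error(ppm_error(1, 0), "positive")
})

test_that("b and y ladders for GG match residue arithmetic", {
  expect_equal(fragment_series("GG", "b"), 57.02146 + 1.007276,
               tolerance = 5e-4)
  expect_equal(fragment_series("GG", "y"), 57.02146 + 18.010565 + 1.007276,
               tolerance = 5e-4)
  expect_length(fragment_series("ETLYGQEIDQASFLTILK", "b"), 17)
  expect_error(fragment_series("GG", "z"), "arg")
})

test_that("b/y complementarity holds at every cleavage site", {
  tab <- amino_acid_masses()
  set.seed(11)
  aa <- names(tab$residues)
  for (rep in 1:20) {
    pep <- paste(sample(aa, sample(4:25, 1), replace = TRUE), collapse = "")
    b <- fragment_series(pep, "b")
    y <- fragment_series(pep, "y")
    n <- nchar(pep)
    total <- peptide_mass(pep) + 2 * tab$proton
    expect_equal(b + rev(y), rep(total, n - 1), tolerance = 1e-6)
  }
})

test_that("mass is additive over concatenation minus one water", {
  tab <- amino_acid_masses()
  set.seed(12)
  aa <- names(tab$residues)
  for (rep in 1:20) {
    a <- paste(sample(aa, sample(1:15, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(1:15, 1), replace = TRUE), collapse = "")
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - tab$water,
                 tolerance = 1e-9)
  }
})

test_that("fragment charge divides the ladder", {
  b1 <- fragment_series("ELVISLIVESK", "b", 1)
  b2 <- fragment_series("ELVISLIVESK", "b", 2)
  p <- amino_acid_masses()$proton
  expect_equal(b2, (b1 - p + 2 * p) / 2, tolerance = 1e-9)
})

test_that("modification registry round-trips through TSV and JSON", {
  reg <- default_modifications()
  tsv <- tempfile(fileext = ".tsv")
  write.table(reg, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_modifications(tsv), reg)
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(reg, js, digits = NA)
  expect_equal(read_modifications(js), reg)
  bad <- tempfile(fileext = ".tsv")
  write.table(reg[, 1:2], bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_modifications(bad), "columns")
})
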