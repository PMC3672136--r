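make_annot <- function(acc, loc, fun = "other") {
  structure(data.frame(accession = acc, localization = loc,
                       "function" = rep_len(fun, length(acc)),
                       check.names = FALSE, stringsAsFactors = FALSE),
            class = c("annotation_map", "data.frame"))
}

test_that("before/after weighting arithmetic", {
  prof <- data.frame(accession = c("A", "B"), count_HC = c(30L, 10L),
                     count_NSC = 0L)
  annot <- make_annot(c("A", "B"), c("cytoplasm", "nucleus"))
  cp <- profile_categories(prof, annot, axis = "localization")
  expect_equal(cp$proportion_before[cp$category == "cytoplasm"], 0.5)
  expect_equal(cp$proportion_after[cp$category == "cytoplasm"], 0.75)
  expect_equal(cp$proportion_after[cp$category == "nucleus"], 0.25)
})

test_that("unmapped accessions fall into 'not annotated'", {
  prof <- data.frame(accession = c("A", "B"), count_HC = 1L, count_NSC = 0L)
  cp <- profile_categories(prof, make_annot(character(0), character(0)),
                           axis = "localization")
  expect_equal(cp$proportion_before[cp$category == "not annotated"], 1)
})

test_that("count-weighting shifts mass toward high-count categories", {
  prof <- data.frame(accession = sprintf("P%02d", 1:10),
                     count_HC = c(rep(100L, 3), rep(2L, 7)), count_NSC = 0L)
  annot <- make_annot(prof$accession,
                      c(rep("vesicle", 3), rep("cytoplasm", 7)))
  cp <- profile_categories(prof, annot, axis = "localization")
  ves <- cp$category == "vesicle"
  expect_gt(cp$proportion_after[ves], cp$proportion_before[ves])
})

test_that("both weightings normalize to 1 and ignore input order", {
  set.seed(41)
  prof <- data.frame(accession = sprintf("P%02d", 1:30),
                     count_HC = rpois(30, 20) + 1L,
                     count_NSC = rpois(30, 20) + 1L)
  vocab <- category_vocabularies()$localization
  annot <- make_annot(prof$accession, sample(vocab[1:5], 30, replace = TRUE))
  cp <- profile_categories(prof, annot, axis = "localization")
  expect_equal(sum(cp$proportion_before), 1, tolerance = 1e-9)
  expect_equal(sum(cp$proportion_after), 1, tolerance = 1e-9)
  cp2 <- profile_categories(prof[sample(30), ], annot, axis = "localization")
  expect_equal(cp, cp2, ignore_attr = TRUE)
  # equal counts collapse the two weightings
  prof$count_HC <- 7L; prof$count_NSC <- 0L
  cp3 <- profile_categories(prof, annot, axis = "localization",
                            population = "HC")
  expect_equal(cp3$proportion_before, cp3$proportion_after, tolerance = 1e-12)
})

test_that("population argument selects the counting margin", {
  prof <- data.frame(accession = c("A", "B"), count_HC = c(10L, 0L),
                     count_NSC = c(0L, 30L))
  annot <- make_annot(c("A", "B"), c("cytoplasm", "nucleus"))
  hc <- profile_categories(prof, annot, axis = "localization",
                           population = "HC")
  expect_equal(hc$proportion_after[hc$category == "cytoplasm"], 1)
})

test_that("profile differences are in percentage points and sum to zero", {
  prof <- data.frame(accession = sprintf("P%d", 1:4),
                     count_HC = c(9L, 1L, 5L, 5L), count_NSC = c(5L, 5L, 5L, 5L))
  annot <- make_annot(prof$accession,
                      c("vesicle", "cytoplasm", "nucleus", "ER"))
  d0 <- compare_profiles(
    profile_categories(prof, annot, axis = "localization", population = "HC"),
    profile_categories(prof, annot, axis = "localization", population = "HC"))
  expect_true(all(d0$diff_before_pp == 0) && all(d0$diff_after_pp == 0))
  d <- compare_profiles(
    profile_categories(prof, annot, axis = "localization", population = "HC"),
    profile_categories(prof, annot, axis = "localization", population = "NSC"))
  expect_equal(sum(d$diff_before_pp), 0, tolerance = 1e-9)
  expect_equal(sum(d$diff_after_pp), 0, tolerance = 1e-9)
  # constructed shift: vesicle holds 45% of HC counts vs 25% of NSC -> +20 pp
  expect_equal(d$diff_after_pp[d$category == "vesicle"], 20, tolerance = 1e-9)
})

test_that("vocabulary violations are rejected", {
  prof <- data.frame(accession = "A", count_HC = 1L, count_NSC = 0L)
  annot <- make_annot("A", "spaceship")
  expect_error(profile_categories(prof, annot, axis = "localization"),
               "vocabulary")
  expect_error(profile_categories(prof, make_annot("A", "cytoplasm"),
                                  axis = "localization", vocab = character(0)),
               "empty")
  p1 <- profile_categories(prof, make_annot("A", "cytoplasm"),
                           axis = "localization")
  p2 <- p1; p2$category <- rev(p2$category)
  expect_error(compare_profiles(p1, p2), "vocabulary")
})

test_that("annotation TSV reading validates and truncates multi-categories", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("accession\tlocalization\tfunction",
               "P1\tcytoplasm;nucleus\ttrafficking",
               "P2\tvesicle\tenergy metabolism"), f)
  annot <- read_annotations(f)
  expect_identical(annot$localization, c("cytoplasm", "vesicle"))
  writeLines(c("accession\tlocalization\tfunction",
               "P1\tmoon\ttrafficking"), f)
  expect_error(read_annotations(f), "vocabulary")
})
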