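test_that("database generation is deterministic and sized as configured", {
  cfg <- synthetic_config(n_proteins = 50, n_HC_specific = 5,
                          n_NSC_specific = 5, n_HC_enriched = 5,
                          n_NSC_enriched = 5, seed = 3)
  db1 <- generate_database(cfg)
  db2 <- generate_database(cfg)
  expect_identical(db1$sequences, db2$sequences)
  f1 <- tempfile(); f2 <- tempfile()
  write_protein_fasta(db1$sequences, f1)
  write_protein_fasta(db2$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_length(db1$sequences, 50)
  expect_true(all(nchar(db1$sequences) >= 100 & nchar(db1$sequences) <= 600))
  expect_identical(as.vector(table(db1$truth$class)[c("HC_SPECIFIC", "BALANCED")]),
                   c(5L, 30L))
  empty <- generate_database(synthetic_config(n_proteins = 0,
                                              n_HC_specific = 0,
                                              n_NSC_specific = 0,
                                              n_HC_enriched = 0,
                                              n_NSC_enriched = 0))
  expect_length(empty$sequences, 0)
  expect_error(synthetic_config(n_proteins = 10), "exceed")
})

test_that("tryptic digestion cleaves after K/R except before proline", {
  peps <- tryptic_peptides("MKLVPRGSAKWDEER", missed = 0, min_length = 1)
  expect_identical(peps, c("MK", "LVPR", "GSAK", "WDEER"))
  # a K-P junction is protected from cleavage
  expect_identical(tryptic_peptides("MKPVR", missed = 0, min_length = 1),
                   "MKPVR")
  set.seed(13)
  aa <- names(amino_acid_masses()$residues)
  for (i in 1:10) {
    seq <- paste(sample(aa, 200, replace = TRUE), collapse = "")
    for (pep in tryptic_peptides(seq, missed = 0, min_length = 1)) {
      res <- strsplit(pep, "")[[1]]
      # internal residues never present an unprotected cleavage site
      if (length(res) > 1) {
        internal <- res[-length(res)]
        follows <- res[-1]
        expect_false(any(internal %in% c("K", "R") & follows != "P"))
      }
    }
    # digest reassembles the protein
    expect_identical(paste(tryptic_peptides(seq, 0, 1), collapse = ""), seq)
  }
  # missed cleavages concatenate adjacent fully-cleaved peptides
  peps2 <- tryptic_peptides("MKLVPRGSAKWDEER", missed = 1, min_length = 1)
  expect_true(all(c("MKLVPR", "LVPRGSAK", "GSAKWDEER") %in% peps2))
})

test_that("PSM generation is deterministic under the seed", {
  cfg <- synthetic_config(seed = 8, psms_per_run = 300, n_proteins = 60,
                          n_HC_specific = 5, n_NSC_specific = 5,
                          n_HC_enriched = 5, n_NSC_enriched = 5)
  db <- generate_database(cfg)
  s1 <- generate_psms(cfg, db)
  s2 <- generate_psms(cfg, db)
  expect_identical(s1$psms, s2$psms)
  expect_identical(nrow(s1$psms), 300L * 6L)
  expect_true(all(s1$psms$fraction %in% 1:8))
})

test_that("without contamination no HC-specific protein reaches an NSC run", {
  cfg <- synthetic_config(seed = 14, psms_per_run = 2000, n_proteins = 60,
                          n_HC_specific = 10, n_NSC_specific = 10,
                          n_HC_enriched = 5, n_NSC_enriched = 5,
                          contamination_epsilon = 0, decoy_hit_rate = 0)
  sim <- simulate_experiment(cfg)
  hc_specific <- sim$truth$accession[sim$truth$class == "HC_SPECIFIC"]
  nsc_psms <- sim$psms[sim$psms$group == "NSC", ]
  expect_false(any(nsc_psms$proteins %in% hc_specific))
  expect_false(any(sim$psms$is_decoy))  # decoy_hit_rate = 0
})

test_that("contaminated NSC runs draw HC-profile PSMs at the mixture rate", {
  eps <- 0.5
  cfg <- synthetic_config(seed = 15, psms_per_run = 4000, n_proteins = 60,
                          n_HC_specific = 10, n_NSC_specific = 10,
                          n_HC_enriched = 5, n_NSC_enriched = 5,
                          contamination_epsilon = eps, decoy_hit_rate = 0)
  db <- generate_database(cfg)
  sim <- generate_psms(cfg, db)
  pr <- specsort:::abundance_profiles(db$truth, cfg$enrichment_fold)
  hc_specific <- db$truth$class == "HC_SPECIFIC"
  share_HC <- sum(pr$HC[hc_specific]) / sum(pr$HC)
  nsc <- sim$psms[sim$psms$group == "NSC", ]
  observed <- mean(nsc$proteins %in% db$truth$accession[hc_specific])
  expected <- eps * share_HC
  se <- sqrt(expected * (1 - expected) / nrow(nsc))
  expect_lt(abs(observed - expected), 4 * se + 0.005)
})

test_that("enriched proteins accumulate counts near the configured fold", {
  cfg <- synthetic_config(seed = 16, psms_per_run = 4000,
                          contamination_epsilon = 0, decoy_hit_rate = 0)
  db <- digest_database(generate_database(cfg), cfg)
  ratios <- numeric(10)
  for (i in 1:10) {
    cfg$seed <- 400 + i
    sim <- generate_psms(cfg, db)
    prof <- count_spectra(sim$psms)
    enr <- db$truth$accession[db$truth$class == "HC_ENRICHED"]
    sub <- prof[prof$accession %in% enr, ]
    ratios[i] <- sum(sub$count_HC) / sum(sub$count_NSC)
  }
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - cfg$enrichment_fold), 3 * se + 0.3)
})

test_that("simulate_experiment writes the standard artifact files", {
  dir <- tempfile()
  cfg <- synthetic_config(seed = 4, psms_per_run = 200, n_proteins = 30,
                          n_HC_specific = 2, n_NSC_specific = 2,
                          n_HC_enriched = 2, n_NSC_enriched = 2)
  sim <- simulate_experiment(cfg, dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("composite.fasta", "psms.tsv", "truth.tsv")))))
  back <- read_psms(file.path(dir, "psms.tsv"))
  expect_identical(nrow(back), nrow(sim$psms))
  fasta <- read_protein_fasta(file.path(dir, "composite.fasta"))
  expect_length(fasta, 60)  # targets + decoys
})
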