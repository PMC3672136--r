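# Build a minimal valid PSM data frame; every field overridable, recycled
# to the longest argument.
make_psms <- function(peptide = "PEPTIDEK", proteins = "P1", score = 5,
                      group = "HC", experiment_id = 1L, fraction = 1L,
                      charge = 2L, mods = "", exp_mz = 500,
                      spectrum_id = NULL) {
  n <- max(lengths(list(peptide, proteins, score, group, experiment_id,
                        fraction, charge, mods, exp_mz)))
  if (is.null(spectrum_id)) spectrum_id <- sprintf("S%04d", seq_len(n))
  validate_psms(data.frame(
    spectrum_id = spectrum_id,
    experiment_id = rep_len(experiment_id, n),
    group = rep_len(group, n), fraction = rep_len(fraction, n),
    peptide = rep_len(peptide, n), mods = rep_len(mods, n),
    charge = rep_len(charge, n), exp_mz = rep_len(exp_mz, n),
    score = rep_len(score, n), proteins = rep_len(proteins, n),
    stringsAsFactors = FALSE
  ))
}

# Distinct dummy peptides, so proteins can be given controlled numbers of
# unique peptides.
dummy_peptides <- function(n) {
  sprintf("PEPTIDEN%sK", strrep("A", seq_len(n)))
}

# A small default-condition simulation shared by several tests.
small_sim <- function(seed = 42, ...) {
  simulate_experiment(synthetic_config(seed = seed, psms_per_run = 1500,
                                       n_proteins = 120,
                                       n_HC_specific = 8, n_NSC_specific = 8,
                                       n_HC_enriched = 8, n_NSC_enriched = 8,
                                       ...))
}
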