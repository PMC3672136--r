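Package: specsort
Title: Spectral-Count Proteomics of FACS-Sorted Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A label-free shotgun-proteomics pipeline for comparing two
    FACS-purified cell populations, modeled on the comparative analysis of
    sensory hair cells versus non-sensory cells of the inner ear. Provides
    peptide and fragment-ion monoisotopic mass arithmetic, reversed-sequence
    decoy database construction, target-decoy false discovery rate (FDR)
    estimation and cascaded PSM/peptide/protein filtering, spectral-count
    quantification, exclusive/shared protein classification with two-sided
    Fisher's exact reassignment of contamination-masked proteins, and
    spectral-count-weighted category profiling. A synthetic PSM generator
    emulates the 3-versus-3 run, 8-fraction study design with configurable
    cross-contamination, so every stage is testable without raw spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
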