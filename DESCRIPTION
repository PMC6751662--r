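Package: flpscreen
Title: Cross-Species GPCR-Neuropeptide Screening Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cross-species neuropeptide GPCR
    deorphanization screens of the C. elegans FLP/NPR and human NPY/RFamide
    systems. Simulates second-messenger plate-reader data (IP accumulation,
    CRE-luciferase cAMP, forskolin-stimulated cAMP inhibition) from explicit
    ground-truth pharmacology, normalizes raw signals to fold-of-basal or
    fold-of-forskolin, calls peptide-receptor activation with
    threshold-plus-Dunnett rules, grades two-concentration screens into a
    five-grade interaction matrix with partial-agonist flagging, determines
    G-protein coupling preferences, fits four-parameter logistic
    concentration-response curves with reference-normalized Emax, classifies
    RFamide peptides by C-terminal consensus motif, computes chemotaxis
    avoidance and bordering statistics for worm behavioral assays, and
    nominates candidate ligands by intersecting the interaction matrix with
    heterologous-rescue results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    multcomp,
    emmeans,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
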