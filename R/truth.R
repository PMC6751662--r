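#' Pathway tags understood by the simulator and callers
#'
#' Five second-messenger readouts: CRE-luciferase cAMP accumulation (Gs),
#' forskolin-stimulated cAMP inhibition (Gi/o), and three inositol-phosphate
#' channels -- endogenous Gq, promiscuous Galpha16, and the chimeric
#' GalphaDelta6qi4myr that reroutes Gi/o-preferring receptors to the PLC/IP
#' readout.
#'
#' @export
flp_pathways <- function() {
  c("Gs_cAMP", "Gio_cAMP_fsk", "Gq_IP", "G16_IP", "Dqi4myr_IP")
}

#' Pathways read out as inhibition of a forskolin-stimulated signal
#' @keywords internal
inhibitory_pathways <- function() "Gio_cAMP_fsk"

#' Ground-truth pharmacology for screen simulation
#'
#' Bundles per-pair four-parameter-logistic truth with per-receptor signal
#' windows. Pairs absent from `pharmacology` are inert (emax = 0).
#'
#' @param pharmacology Tibble/data frame with columns `receptor`, `peptide`,
#'   `pathway`, `ec50` (molar), `emax` (fraction of the receptor window in
#'   0..1; for the Gi/o readout, the maximal fractional inhibition of the
#'   forskolin signal), `hill` (> 0, defaults to 1 when missing).
#' @param receptor_windows Tibble with columns `receptor`, `pathway`,
#'   `basal` (arbitrary units > 0) and `window` (maximal fold-of-basal at
#'   full activation, > 1).
#' @param forskolin_fold Fold over basal of the forskolin control
#'   (Gi/o readout only). Default 20.
#'
#' @return An object of class `screen_truth`.
#' @export
screen_truth <- function(pharmacology, receptor_windows, forskolin_fold = 20) {
  pharmacology <- tibble::as_tibble(pharmacology)
  receptor_windows <- tibble::as_tibble(receptor_windows)
  if (!"hill" %in% names(pharmacology)) pharmacology$hill <- 1
  pharmacology$hill[is.na(pharmacology$hill)] <- 1
  need <- c("receptor", "peptide", "pathway", "ec50", "emax", "hill")
  miss <- setdiff(need, names(pharmacology))
  if (length(miss) > 0) {
    stop("pharmacology is missing columns: ", paste(miss, collapse = ", "))
  }
  miss <- setdiff(c("receptor", "pathway", "basal", "window"), names(receptor_windows))
  if (length(miss) > 0) {
    stop("receptor_windows is missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(c(pharmacology$pathway, receptor_windows$pathway)), flp_pathways())
  if (length(bad) > 0) {
    stop("unknown pathway tag(s): ", paste(bad, collapse = ", "))
  }
  stopifnot(
    all(pharmacology$ec50 > 0),
    all(pharmacology$emax >= 0 & pharmacology$emax <= 1),
    all(pharmacology$hill > 0),
    all(receptor_windows$basal > 0),
    all(receptor_windows$window > 1),
    forskolin_fold > 1
  )
  structure(
    list(
      pharmacology = pharmacology[need],
      receptor_windows = receptor_windows,
      forskolin_fold = forskolin_fold
    ),
    class = "screen_truth"
  )
}

#' @export
print.screen_truth <- function(x, ...) {
  cat("<screen_truth> ",
      nrow(x$pharmacology), " active pair(s), ",
      nrow(x$receptor_windows), " receptor x pathway window(s), ",
      "forskolin fold ", x$forskolin_fold, "\n", sep = "")
  print(x$pharmacology, n = 10)
  invisible(x)
}

#' Screen design: concentrations, replication and noise
#'
#' Defaults mirror the two-concentration primary screen (100 nM and 10 uM)
#' run as at least three independent experiments in technical triplicate.
#'
#' @param concentrations Molar peptide concentrations, strictly positive.
#' @param n_experiments Independent experiments (biological replicates).
#' @param n_replicates Technical replicates (wells) per condition and
#'   experiment.
#' @param noise_cv Per-well multiplicative log-normal coefficient of
#'   variation.
#' @param experiment_cv Between-experiment log-normal scale CV applied to a
#'   whole experiment's signals (plate-to-plate variability). Cancels under
#'   fold-of-control normalization.
#'
#' @return An object of class `screen_design`.
#' @export
screen_design <- function(concentrations = c(1e-7, 1e-5),
                          n_experiments = 3,
                          n_replicates = 3,
                          noise_cv = 0.10,
                          experiment_cv = 0.05) {
  if (any(concentrations <= 0)) stop("concentrations must be strictly positive")
  concentrations <- sort(unique(concentrations))
  stopifnot(n_experiments >= 1, n_replicates >= 1, noise_cv >= 0, experiment_cv >= 0)
  structure(
    list(
      concentrations = concentrations,
      n_experiments = as.integer(n_experiments),
      n_replicates = as.integer(n_replicates),
      noise_cv = noise_cv,
      experiment_cv = experiment_cv
    ),
    class = "screen_design"
  )
}

#' Literature reference pharmacology of potent FLP/NPY pairs
#'
#' EC50 and relative-Emax values reported for the most potent ligand-receptor
#' interactions of the C. elegans FLP/NPR and human NPY systems in HEK293
#' second-messenger assays: FLP-21 and FLP-14 at NPR-1 (Gi/o cAMP
#' inhibition; FLP-14 is a high-affinity partial agonist), and FLP-34-1,
#' FLP-34-2, human PYY and NPY at NPR-11 (GalphaDelta6qi4myr IP readout).
#' Emax is expressed in percent of the FLP-21-induced response, the reference
#' agonist convention used for these receptors.
#'
#' @return Tibble with columns `receptor`, `peptide`, `pathway`, `ec50`
#'   (molar), `emax_pct_reference`, `reference_peptide`.
#' @export
reference_pharmacology <- function() {
  tibble::tribble(
    ~receptor, ~peptide,   ~pathway,       ~ec50,   ~emax_pct_reference, ~reference_peptide,
    "NPR-1",   "FLP-21",   "Gio_cAMP_fsk", 1e-9,    100,                 "FLP-21",
    "NPR-1",   "FLP-14",   "Gio_cAMP_fsk", 24e-9,   53,                  "FLP-21",
    "NPR-11",  "FLP-34-1", "Dqi4myr_IP",   19e-9,   100,                 "FLP-21",
    "NPR-11",  "FLP-34-2", "Dqi4myr_IP",   0.7e-9,  100,                 "FLP-21",
    "NPR-11",  "PYY",      "Dqi4myr_IP",   24e-9,   86,                  "FLP-21",
    "NPR-11",  "NPY",      "Dqi4myr_IP",   256e-9,  49,                  "FLP-21"
  )
}

#' Behavioral ground truth for worm-count simulations
#'
#' @param genotypes Tibble with one row per genotype. For quadrant
#'   (avoidance) assays: `genotype`, `p_mesa` (probability a scored worm ends
#'   in a methyl-salicylate quadrant), optional `p_lost` (fraction of placed
#'   worms never scored, default 0), `n_worms` per plate, `n_plates`.
#'   For bordering assays: `genotype`, `p_border`, `n_worms`, `n_plates`.
#'
#' @return An object of class `behavior_truth`.
#' @export
behavior_truth <- function(genotypes) {
  genotypes <- tibble::as_tibble(genotypes)
  if (!"genotype" %in% names(genotypes)) stop("genotypes needs a `genotype` column")
  probs <- intersect(c("p_mesa", "p_border", "p_lost"), names(genotypes))
  for (p in probs) {
    v <- genotypes[[p]]
    if (any(v < 0 | v > 1)) stop("probability column `", p, "` outside [0, 1]")
  }
  if (!"p_lost" %in% names(genotypes) && "p_mesa" %in% names(genotypes)) {
    genotypes$p_lost <- 0
  }
  stopifnot(all(genotypes$n_worms > 0), all(genotypes$n_plates >= 1))
  structure(list(genotypes = genotypes), class = "behavior_truth")
}
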