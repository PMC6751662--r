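#' Example screen truth with one pair per matrix grade
#'
#' A single receptor (window 10x on the endogenous-Gq IP readout) screened
#' against seven peptides whose potencies and efficacies were chosen so
#' that, noise-free, the two-concentration screen assigns each grade
#' exactly once -- including one high-affinity partial agonist that
#' triggers the asterisk flag -- plus one inert pair.
#'
#' @return A [screen_truth()].
#' @export
example_screen_truth <- function() {
  screen_truth(
    pharmacology = tibble::tribble(
      ~receptor, ~peptide,   ~pathway, ~ec50, ~emax, ~hill,
      "R1",      "pep_v",    "Gq_IP",  1e-8,  1,    1,
      "R1",      "pep_iv",   "Gq_IP",  5e-7,  1,    1,
      "R1",      "pep_iii",  "Gq_IP",  1e-7,  0.7,  1,
      "R1",      "pep_ast",  "Gq_IP",  1e-8,  0.5,  1,
      "R1",      "pep_ii",   "Gq_IP",  5e-6,  1,    1,
      "R1",      "pep_i",    "Gq_IP",  5e-5,  1,    1,
      "R1",      "pep_none", "Gq_IP",  1e-6,  0,    1
    ),
    receptor_windows = tibble::tibble(receptor = "R1", pathway = "Gq_IP",
                                      basal = 100, window = 10)
  )
}

#' Study conditions for the potency-recovery benchmark
#'
#' Ground truth assembled from [reference_pharmacology()]: the Gi/o cAMP
#' readout of NPR-1 (FLP-21 reference agonist, FLP-14 partial agonist) and
#' the chimeric-Galpha IP readout of NPR-11 (FLP-21 reference; FLP-34-1,
#' FLP-34-2, PYY, NPY test ligands). The FLP-21 potency at NPR-11 is not a
#' literature value and is set to 50 nM, a typical sub-100-nM potency for
#' a reference agonist on this receptor; it only anchors the reference
#' window and does not enter the reported recoveries.
#'
#' @return List with `truth` ([screen_truth()]), `pairs` (fit request for
#'   [fit_dose_response()]) and `design` (8-point curves, CV 10 percent,
#'   3 experiments x triplicate).
#' @export
recovery_conditions <- function() {
  ref <- reference_pharmacology()
  pharm <- dplyr::bind_rows(
    dplyr::transmute(ref, .data$receptor, .data$peptide, .data$pathway,
                     ec50 = .data$ec50, emax = .data$emax_pct_reference / 100,
                     hill = 1),
    tibble::tibble(receptor = "NPR-11", peptide = "FLP-21",
                   pathway = "Dqi4myr_IP", ec50 = 50e-9, emax = 1, hill = 1)
  )
  truth <- screen_truth(
    pharmacology = pharm,
    receptor_windows = tibble::tibble(
      receptor = c("NPR-1", "NPR-11"),
      pathway = c("Gio_cAMP_fsk", "Dqi4myr_IP"),
      basal = 100, window = 10),
    forskolin_fold = 20
  )
  pairs <- dplyr::select(ref, "receptor", "peptide", "pathway",
                         reference_peptide = "reference_peptide")
  design <- screen_design(concentrations = 10^seq(-11, -4.5, length.out = 8),
                          n_experiments = 3, n_replicates = 3,
                          noise_cv = 0.10, experiment_cv = 0.05)
  list(truth = truth, pairs = pairs, design = design)
}

#' Potency and relative-Emax recovery under the study conditions
#'
#' Repeatedly simulates full concentration-response screens from
#' [recovery_conditions()], fits every reference pair with [fit_4pl()] on
#' fold-normalized responses, and summarises per pair the median fitted
#' log10 EC50 and relative Emax across seeds.
#'
#' @param n_seeds Number of independent simulated campaigns.
#' @param seed Base seed; campaign `k` uses `seed * 1000 + k`.
#' @return Tibble per pair: `receptor`, `peptide`, `true_ec50`,
#'   `true_emax_pct`, `median_log10_ec50`, `median_ec50`,
#'   `median_emax_pct`, `n_converged`.
#' @export
benchmark_ec50_recovery <- function(n_seeds = 50, seed = 1) {
  cond <- recovery_conditions()
  per_seed <- purrr::map_dfr(seq_len(n_seeds), function(k) {
    folds <- normalize_folds(
      simulate_screen(cond$truth, cond$design, seed = seed * 1000 + k))
    fit_dose_response(folds, cond$pairs) |>
      dplyr::select("receptor", "peptide", "ec50", "emax_pct_reference",
                    "converged") |>
      dplyr::mutate(rep = k)
  })
  ref <- reference_pharmacology()
  per_seed |>
    dplyr::filter(.data$converged) |>
    dplyr::summarise(
      median_log10_ec50 = stats::median(log10(.data$ec50)),
      median_ec50 = stats::median(.data$ec50),
      median_emax_pct = stats::median(.data$emax_pct_reference),
      n_converged = dplyr::n(),
      .by = c("receptor", "peptide")
    ) |>
    dplyr::left_join(
      dplyr::select(ref, "receptor", "peptide", true_ec50 = "ec50",
                    true_emax_pct = "emax_pct_reference"),
      by = c("receptor", "peptide")
    )
}

#' Grade recovery of the example truth under screen noise
#'
#' Re-simulates the two-concentration screen of [example_screen_truth()]
#' at the given noise level `n_seeds` times, re-calls the matrix each
#' time, and compares grades (and the asterisk flag) against the
#' noise-free calls of the same truth.
#'
#' @param n_seeds Number of simulated screens.
#' @param seed Base seed.
#' @param noise_cv Per-well CV of the noisy screens.
#' @return List: `expected` (noise-free calls), `agreement` (fraction of
#'   cells across all seeds whose grade and asterisk both match),
#'   `per_seed` (fraction per seed).
#' @export
benchmark_matrix_recovery <- function(n_seeds = 100, seed = 1,
                                      noise_cv = 0.05) {
  truth <- example_screen_truth()
  spec <- tibble::tibble(receptor = "R1", species = "C. elegans",
                         pathway = "Gq_IP")
  call_once <- function(design, s) {
    folds <- normalize_folds(simulate_screen(truth, design, seed = s))
    call_activation(folds, spec) |>
      dplyr::select("peptide", "grade", "asterisk") |>
      dplyr::arrange(.data$peptide)
  }
  expected <- call_once(screen_design(noise_cv = 0, experiment_cv = 0), 1)
  per_seed <- vapply(seq_len(n_seeds), function(k) {
    got <- call_once(screen_design(noise_cv = noise_cv, experiment_cv = 0.05),
                     seed * 1000 + k)
    mean(as.character(got$grade) == as.character(expected$grade) &
           got$asterisk == expected$asterisk)
  }, numeric(1))
  list(expected = expected, agreement = mean(per_seed), per_seed = per_seed)
}

#' Empirical type-I error of the activation test under the null
#'
#' Simulates strata in which every peptide is inert (emax 0) and counts
#' how often [test_activation()] flags a peptide condition as
#' significantly different from the control.
#'
#' @param n_sims Number of null strata.
#' @param seed Base seed.
#' @param n_peptides Inert peptides per stratum.
#' @return List: `per_comparison` (fraction of false-positive
#'   comparisons), `familywise` (fraction of strata with at least one),
#'   `n_comparisons` total comparisons performed.
#' @export
benchmark_type1_activation <- function(n_sims = 1000, seed = 1,
                                       n_peptides = 4) {
  truth <- screen_truth(
    pharmacology = tibble::tibble(
      receptor = "R1", peptide = paste0("null", seq_len(n_peptides)),
      pathway = "Gq_IP", ec50 = 1e-8, emax = 0, hill = 1),
    receptor_windows = tibble::tibble(receptor = "R1", pathway = "Gq_IP",
                                      basal = 100, window = 10)
  )
  design <- screen_design(noise_cv = 0.10, experiment_cv = 0.05)
  flags <- purrr::map(seq_len(n_sims), function(k) {
    folds <- normalize_folds(simulate_screen(truth, design,
                                             seed = seed * 2000 + k))
    test_activation(folds)$significant
  })
  list(per_comparison = mean(unlist(flags)),
       familywise = mean(vapply(flags, any, logical(1))),
       n_comparisons = length(unlist(flags)))
}

#' Empirical type-I error of behavioral group comparisons under the null
#'
#' Simulates avoidance assays in which all genotypes share the same
#' quadrant preference and counts falsely significant comparisons against
#' the reference genotype.
#'
#' @param n_sims Number of null experiments.
#' @param seed Base seed.
#' @return List as in [benchmark_type1_activation()].
#' @export
benchmark_type1_groups <- function(n_sims = 1000, seed = 1) {
  truth <- behavior_truth(tibble::tibble(
    genotype = c("ref", "g1", "g2"), p_mesa = 0.3,
    n_worms = 100, n_plates = 6))
  flags <- purrr::map(seq_len(n_sims), function(k) {
    plates <- simulate_avoidance_plates(truth, seed = seed * 3000 + k)
    cmp <- compare_groups(avoidance_index(plates), "avoidance_index",
                          reference = "ref")
    cmp$significant[cmp$genotype != "ref"]
  })
  list(per_comparison = mean(unlist(flags)),
       familywise = mean(vapply(flags, any, logical(1))),
       n_comparisons = length(unlist(flags)))
}
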