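#' Four-parameter logistic fractional occupancy
#'
#' @param conc Molar concentration(s).
#' @param ec50 Half-maximal concentration (molar).
#' @param hill Hill slope (> 0).
#' @return `conc^hill / (conc^hill + ec50^hill)` evaluated stably in log space.
#' @keywords internal
hill_occupancy <- function(conc, ec50, hill) {
  # computed as a logistic in log-concentration to avoid overflow at high hill
  1 / (1 + exp(hill * (log(ec50) - log(conc))))
}

#' Mean plate-reader signal under the readout model
#'
#' Stimulatory readouts (Gs cAMP, all IP channels):
#' `basal * (1 + (window - 1) * emax * occ)`.
#' Forskolin-stimulated cAMP inhibition (Gi/o):
#' `basal * forskolin_fold * (1 - emax * occ)`, where `occ` is the 4PL
#' fractional occupancy at the given concentration.
#'
#' @keywords internal
model_mean_signal <- function(pathway, conc, basal, window, forskolin_fold,
                              ec50, emax, hill) {
  occ <- ifelse(conc > 0, hill_occupancy(pmax(conc, .Machine$double.xmin), ec50, hill), 0)
  occ[emax == 0] <- 0
  ifelse(
    pathway %in% inhibitory_pathways(),
    basal * forskolin_fold * (1 - emax * occ),
    basal * (1 + (window - 1) * emax * occ)
  )
}

lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))  # unit mean
}

#' Simulate a second-messenger screening campaign
#'
#' Emits one row per well in long plate format. Every receptor x pathway x
#' experiment stratum carries buffer control wells; strata on the
#' forskolin-stimulated cAMP readout additionally carry forskolin control
#' wells. Peptide wells are laid out per concentration in `design`. Noise is
#' multiplicative log-normal per well (unit mean, CV `design$noise_cv`) on
#' top of an optional per-experiment log-normal scale factor.
#'
#' @param truth A [screen_truth()] object.
#' @param design A [screen_design()] object.
#' @param peptides Optional character vector of peptides to screen; defaults
#'   to every peptide named in the truth. Peptides without a truth entry for
#'   a receptor x pathway are simulated as inert.
#' @param seed Integer seed; identical seeds give identical records.
#'
#' @return Tibble of plate records: `receptor`, `pathway`, `peptide`
#'   (control wells are tagged `"buffer"` / `"forskolin"`), `conc_M` (0 for
#'   controls), `experiment`, `replicate`, `signal`.
#' @export
simulate_screen <- function(truth, design, peptides = NULL, seed = NULL) {
  stopifnot(inherits(truth, "screen_truth"), inherits(design, "screen_design"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(peptides)) peptides <- unique(truth$pharmacology$peptide)

  strata <- truth$receptor_windows
  conds <- tidyr::expand_grid(
    strata[c("receptor", "pathway", "basal", "window")],
    peptide = peptides,
    conc_M = design$concentrations
  )
  controls <- dplyr::bind_rows(
    dplyr::mutate(strata[c("receptor", "pathway", "basal", "window")],
                  peptide = "buffer", conc_M = 0),
    strata |>
      dplyr::filter(.data$pathway %in% inhibitory_pathways()) |>
      dplyr::select("receptor", "pathway", "basal", "window") |>
      dplyr::mutate(peptide = "forskolin", conc_M = 0)
  )
  conds <- dplyr::bind_rows(conds, controls) |>
    dplyr::left_join(truth$pharmacology,
                     by = c("receptor", "pathway", "peptide")) |>
    dplyr::mutate(
      ec50 = dplyr::coalesce(.data$ec50, 1),
      emax = dplyr::coalesce(.data$emax, 0),
      hill = dplyr::coalesce(.data$hill, 1)
    )
  # buffer wells on the Gi/o readout measure unstimulated cAMP (basal);
  # every other control / inert well follows the readout model
  conds$mu <- model_mean_signal(conds$pathway, conds$conc_M, conds$basal,
                                conds$window, truth$forskolin_fold,
                                conds$ec50, conds$emax, conds$hill)
  is_gio_buffer <- conds$pathway %in% inhibitory_pathways() & conds$peptide == "buffer"
  conds$mu[is_gio_buffer] <- conds$basal[is_gio_buffer]

  wells <- tidyr::expand_grid(
    conds[c("receptor", "pathway", "peptide", "conc_M", "mu")],
    experiment = seq_len(design$n_experiments),
    replicate = seq_len(design$n_replicates)
  )
  exp_scale <- lognormal_factor(design$n_experiments, design$experiment_cv)
  wells$signal <- wells$mu * exp_scale[wells$experiment] *
    lognormal_factor(nrow(wells), design$noise_cv)
  wells |>
    dplyr::select("receptor", "pathway", "peptide", "conc_M",
                  "experiment", "replicate", "signal") |>
    dplyr::arrange(.data$receptor, .data$pathway, .data$peptide,
                   .data$conc_M, .data$experiment, .data$replicate)
}

#' Simulate quadrant-assay plates (methyl-salicylate avoidance)
#'
#' Each plate places `n_worms` animals; a fraction `p_lost` is never scored,
#' the rest land in methyl-salicylate (MeSa) or ethanol (EOH) quadrants with
#' probability `p_mesa` / `1 - p_mesa` per worm, independently.
#'
#' @param truth A [behavior_truth()] with `p_mesa` (and optionally `p_lost`).
#' @param seed Integer seed.
#' @return Tibble of quadrant counts: `plate`, `genotype`, `n_mesa`,
#'   `n_eoh`, `n_total` (worms placed on the plate).
#' @export
simulate_avoidance_plates <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "behavior_truth"))
  if (!"p_mesa" %in% names(truth$genotypes)) {
    stop("truth lacks `p_mesa`; did you mean simulate_bordering_plates()?")
  }
  if (!is.null(seed)) set.seed(seed)
  g <- truth$genotypes
  purrr::pmap_dfr(
    list(g$genotype, g$p_mesa, g$p_lost, g$n_worms, g$n_plates),
    function(genotype, p_mesa, p_lost, n_worms, n_plates) {
      if (n_worms <= 0) stop("n_worms must be positive")
      purrr::map_dfr(seq_len(n_plates), function(i) {
        dest <- stats::rmultinom(1, n_worms,
                                 c(mesa = (1 - p_lost) * p_mesa,
                                   eoh = (1 - p_lost) * (1 - p_mesa),
                                   lost = p_lost))
        tibble::tibble(
          plate = paste0(genotype, "_p", i), genotype = genotype,
          n_mesa = dest["mesa", 1], n_eoh = dest["eoh", 1],
          n_total = n_worms
        )
      })
    }
  )
}

#' Simulate lawn-bordering plates
#'
#' Each worm independently ends within the 2 mm border zone of the bacterial
#' lawn with probability `p_border`.
#'
#' @param truth A [behavior_truth()] with `p_border`.
#' @param seed Integer seed.
#' @return Tibble of lawn counts: `plate`, `genotype`, `n_border`, `n_total`.
#' @export
simulate_bordering_plates <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "behavior_truth"))
  if (!"p_border" %in% names(truth$genotypes)) {
    stop("truth lacks `p_border`; did you mean simulate_avoidance_plates()?")
  }
  if (!is.null(seed)) set.seed(seed)
  g <- truth$genotypes
  purrr::pmap_dfr(
    list(g$genotype, g$p_border, g$n_worms, g$n_plates),
    function(genotype, p_border, n_worms, n_plates) {
      if (n_worms <= 0) stop("n_worms must be positive")
      tibble::tibble(
        plate = paste0(genotype, "_p", seq_len(n_plates)),
        genotype = genotype,
        n_border = stats::rbinom(n_plates, n_worms, p_border),
        n_total = n_worms
      )
    }
  )
}
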