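control_tag_for <- function(pathway) {
  ifelse(pathway %in% inhibitory_pathways(), "forskolin", "buffer")
}

#' Normalize raw plate signals to fold of control
#'
#' Within each receptor x pathway x experiment stratum, every well is
#' divided by that experiment's control mean: the buffer mean for
#' stimulatory readouts (fold of basal), the forskolin-control mean for the
#' forskolin-stimulated cAMP readout (fold of forskolin). Multiplicative
#' experiment-level scale effects cancel exactly under this normalization.
#'
#' @param records Long plate tibble as produced by [simulate_screen()] or
#'   read with [read_plate_table()].
#' @return Per-well tibble with columns of `records` plus `fold` and
#'   `is_control`; raw `signal` is retained.
#' @export
normalize_folds <- function(records) {
  need <- c("receptor", "pathway", "peptide", "conc_M", "experiment", "signal")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) stop("plate table missing columns: ",
                             paste(miss, collapse = ", "))
  bad <- setdiff(unique(records$pathway), flp_pathways())
  if (length(bad) > 0) stop("unknown pathway tag(s): ", paste(bad, collapse = ", "))

  records <- dplyr::mutate(records, .ctrl = control_tag_for(.data$pathway))
  ctrl <- records |>
    dplyr::filter(.data$peptide == .data$.ctrl) |>
    dplyr::summarise(ctrl_mean = mean(.data$signal),
                     .by = c("receptor", "pathway", "experiment"))
  # every stratum must carry its control wells
  strata <- dplyr::distinct(records, .data$receptor, .data$pathway, .data$experiment)
  missing <- dplyr::anti_join(strata, ctrl, by = c("receptor", "pathway", "experiment"))
  if (nrow(missing) > 0) {
    stop("missing control wells for stratum: ",
         paste(missing$receptor, missing$pathway,
               paste0("experiment ", missing$experiment), collapse = "; "))
  }
  records |>
    dplyr::left_join(ctrl, by = c("receptor", "pathway", "experiment")) |>
    dplyr::mutate(fold = .data$signal / .data$ctrl_mean,
                  is_control = .data$peptide %in% c("buffer", "forskolin")) |>
    dplyr::select(-".ctrl", -"ctrl_mean")
}

#' Summarise normalized responses across experiments
#'
#' Per-experiment condition means are computed first (the experiment is the
#' unit of replication), then aggregated as mean +/- SEM across experiments.
#'
#' @param folds Output of [normalize_folds()].
#' @return Tibble per receptor x pathway x peptide x concentration with
#'   `fold_mean`, `fold_sem`, `n` (number of experiments).
#' @export
fold_summary <- function(folds) {
  folds |>
    dplyr::summarise(fold = mean(.data$fold),
                     .by = c("receptor", "pathway", "peptide", "conc_M", "experiment")) |>
    dplyr::summarise(
      fold_mean = mean(.data$fold),
      fold_sem = stats::sd(.data$fold) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .by = c("receptor", "pathway", "peptide", "conc_M")
    )
}
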