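#' Declare a heterologous-rescue panel
#'
#' Receptors that did or did not restore the in vivo phenotype of the target
#' receptor's null mutant when expressed in its place.
#'
#' @param target Receptor whose in vivo function is being mapped.
#' @param rescuers Heterologous receptors that rescued the phenotype
#'   (non-empty).
#' @param non_rescuers Receptors that failed to rescue (specificity
#'   controls).
#' @return Object of class `rescue_panel`.
#' @export
rescue_panel <- function(target, rescuers, non_rescuers = character()) {
  if (length(rescuers) == 0) stop("rescuing receptor set must be non-empty")
  all_ids <- c(target, rescuers, non_rescuers)
  if (anyDuplicated(all_ids)) stop("target, rescuers and non-rescuers must be disjoint")
  structure(list(target = target, rescuers = rescuers,
                 non_rescuers = non_rescuers),
            class = "rescue_panel")
}

#' Nominate candidate in vivo ligands by matrix intersection
#'
#' A peptide is a candidate for the target receptor's in vivo function when
#' it activates the target AND every heterologous receptor capable of
#' substituting that function -- the rationale being that whichever ligand
#' drives the behavior must act through all receptors that restore it.
#' Partial-agonist (asterisk) cells count as activation. With
#' `exclude_non_rescuers = TRUE`, peptides activating every non-rescuing
#' receptor are additionally removed (a stricter specificity filter).
#'
#' @param matrix An [build_interaction_matrix()] result (or its tibble).
#' @param panel A [rescue_panel()].
#' @param min_grade Minimal grade counting as activation (`"i"` = any).
#' @param exclude_non_rescuers Apply the specificity filter.
#' @return Tibble of candidates sorted strongest first by the minimal grade
#'   across the required receptors: `peptide`, `min_grade`, plus one grade
#'   column per required receptor.
#' @export
infer_candidates <- function(matrix, panel, min_grade = "i",
                             exclude_non_rescuers = FALSE) {
  stopifnot(inherits(panel, "rescue_panel"),
            min_grade %in% setdiff(grade_levels(), "none"))
  required <- c(panel$target, panel$rescuers)
  present <- unique(as.character(matrix$receptor))
  absent <- setdiff(c(required, if (exclude_non_rescuers) panel$non_rescuers),
                    present)
  if (length(absent) > 0) {
    stop("receptor(s) absent from matrix: ", paste(absent, collapse = ", "))
  }
  g <- matrix |>
    dplyr::mutate(
      peptide = as.character(.data$peptide),
      receptor = as.character(.data$receptor),
      grade_i = as.integer(factor(as.character(.data$grade),
                                  levels = grade_levels())) - 1L
    )
  min_i <- match(min_grade, grade_levels()) - 1L
  per_pep <- g |>
    dplyr::filter(.data$receptor %in% required) |>
    dplyr::summarise(min_grade_i = min(.data$grade_i),
                     .by = "peptide") |>
    dplyr::filter(.data$min_grade_i >= min_i)
  if (exclude_non_rescuers && length(panel$non_rescuers) > 0) {
    hits_all_nr <- g |>
      dplyr::filter(.data$receptor %in% panel$non_rescuers) |>
      dplyr::summarise(all_active = min(.data$grade_i) >= min_i,
                       .by = "peptide") |>
      dplyr::filter(.data$all_active)
    per_pep <- dplyr::anti_join(per_pep, hits_all_nr, by = "peptide")
  }
  grades_wide <- g |>
    dplyr::filter(.data$receptor %in% required) |>
    dplyr::mutate(cell = paste0(as.character(.data$grade),
                                ifelse(.data$asterisk, "*", ""))) |>
    dplyr::select("peptide", "receptor", "cell") |>
    tidyr::pivot_wider(names_from = "receptor", values_from = "cell")
  per_pep |>
    dplyr::mutate(min_grade = grade_levels()[.data$min_grade_i + 1L]) |>
    dplyr::arrange(dplyr::desc(.data$min_grade_i), .data$peptide) |>
    dplyr::left_join(grades_wide, by = "peptide") |>
    dplyr::select("peptide", "min_grade", dplyr::all_of(required))
}
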