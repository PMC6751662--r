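#' Read / write long-format plate tables
#'
#' Tab-separated, one row per well, columns `receptor`, `pathway`,
#' `peptide`, `conc_M` (molar, scientific notation; 0 for control wells),
#' `experiment`, `replicate`, `signal`. Round-trips losslessly with
#' [simulate_screen()] output.
#'
#' @param records Plate tibble.
#' @param path File path.
#' @name plate_table
NULL

#' @rdname plate_table
#' @export
write_plate_table <- function(records, path) {
  readr::write_tsv(dplyr::mutate(records,
                                 conc_M = format(.data$conc_M, scientific = TRUE,
                                                 digits = 15, trim = TRUE)),
                   path)
  invisible(path)
}

#' @rdname plate_table
#' @export
read_plate_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           receptor = "c", pathway = "c", peptide = "c",
                           conc_M = "d", experiment = "i", replicate = "i",
                           signal = "d"))
  need <- c("receptor", "pathway", "peptide", "conc_M", "experiment",
            "replicate", "signal")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0) {
    stop("malformed plate table ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  if (nrow(out) == 0) stop("empty plate table: ", path)
  out
}

#' Serialize an interaction matrix
#'
#' TSV export writes one row per cell with the grade as a token in
#' `0/i/ii/iii/iv/v` and a logical asterisk column; JSON export keeps the
#' full call objects plus the panel ordering so the matrix round-trips
#' losslessly.
#'
#' @param matrix An interaction matrix.
#' @param path File path.
#' @name matrix_io
NULL

#' @rdname matrix_io
#' @export
write_matrix_tsv <- function(matrix, path) {
  matrix |>
    dplyr::mutate(
      grade = ifelse(as.character(.data$grade) == "none", "0",
                     as.character(.data$grade)),
      peptide = as.character(.data$peptide),
      receptor = as.character(.data$receptor)
    ) |>
    dplyr::select("peptide", "receptor", "grade", "asterisk") |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname matrix_io
#' @export
write_matrix_json <- function(matrix, path) {
  payload <- list(
    peptides = levels(matrix$peptide),
    receptors = levels(matrix$receptor),
    cells = dplyr::mutate(tibble::as_tibble(matrix),
                          peptide = as.character(.data$peptide),
                          receptor = as.character(.data$receptor),
                          grade = as.character(.data$grade))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_matrix_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- tibble::as_tibble(payload$cells)
  cells$grade <- factor(cells$grade, levels = grade_levels(), ordered = TRUE)
  cells$peptide <- factor(cells$peptide, levels = payload$peptides)
  cells$receptor <- factor(cells$receptor, levels = payload$receptors)
  structure(dplyr::arrange(cells, .data$peptide, .data$receptor),
            class = c("interaction_matrix", class(cells)))
}

#' Read / write peptide panels as FASTA
#'
#' Amidation is encoded as a trailing `" a"` flag in the description line
#' (e.g. `>FLP-21 a C. elegans`); the token after the flag, when present,
#' is the species. Requires the Biostrings package.
#'
#' @param panel A [peptide_panel()] tibble.
#' @param path File path.
#' @name peptide_fasta
NULL

#' @rdname peptide_fasta
#' @export
write_peptide_fasta <- function(panel, path) {
  rlang::check_installed("Biostrings")
  set <- Biostrings::AAStringSet(panel$sequence)
  names(set) <- paste0(panel$id, ifelse(panel$amidated, " a", " free"),
                       " ", panel$species)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname peptide_fasta
#' @export
read_peptide_fasta <- function(path) {
  rlang::check_installed("Biostrings")
  set <- Biostrings::readAAStringSet(path)
  header <- names(set)
  id <- sub("\\s.*$", "", header)
  rest <- sub("^\\S+\\s*", "", header)
  amid_tok <- sub("\\s.*$", "", rest)
  species <- sub("^\\S+\\s*", "", rest)
  peptide_panel(id = id, sequence = unname(as.character(set)),
                amidated = amid_tok == "a",
                species = ifelse(nzchar(species), species, NA_character_))
}

#' Validate and resolve a run configuration
#'
#' Checks a configuration list against the schema the pipeline expects:
#' a `seed`, a `thresholds` block (passed to [call_thresholds()]), a
#' `design` block (passed to [screen_design()]), an optional
#' `sign_convention`, and a `panel` block with `receptors` (data frame with
#' `receptor`, `species`, `pathway`, optional `endogenous_agonist`) and
#' optionally `peptides`. Unknown top-level fields are an error so typos
#' fail loudly.
#'
#' @param config A list, e.g. from [read_run_config()].
#' @return The resolved config with defaults filled in, classed
#'   `run_config`.
#' @export
validate_run_config <- function(config) {
  allowed <- c("seed", "thresholds", "design", "panel", "sign_convention",
               "output_dir")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed) || !is.numeric(config$seed)) {
    stop("config requires a numeric `seed`")
  }
  config$thresholds <- do.call(call_thresholds,
                               as.list(config$thresholds %||% list()))
  config$design <- do.call(screen_design, as.list(config$design %||% list()))
  config$sign_convention <- match.arg(config$sign_convention %||% "as_printed",
                                      c("as_printed", "avoidance_positive"))
  if (!is.null(config$panel)) {
    rec <- tibble::as_tibble(config$panel$receptors)
    miss <- setdiff(c("receptor", "species", "pathway"), names(rec))
    if (length(miss) > 0) {
      stop("panel$receptors missing column(s): ", paste(miss, collapse = ", "))
    }
    bad <- setdiff(rec$pathway, flp_pathways())
    if (length(bad) > 0) stop("unknown pathway tag(s) in panel: ",
                              paste(bad, collapse = ", "))
    config$panel$receptors <- rec
  }
  structure(config, class = "run_config")
}

#' @rdname validate_run_config
#' @param path JSON file path.
#' @export
read_run_config <- function(path) {
  validate_run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname validate_run_config
#' @param config A validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$design <- unclass(out$design)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
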