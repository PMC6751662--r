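AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Default residue classes for C-terminal consensus motifs
#'
#' Aromatic (Omega) and hydrophobic (Psi) residue sets used by
#' [classify_motif()]. The consensus symbols are conventional; the exact
#' residue membership is a configurable choice (whether Omega includes H, or
#' Psi includes G/P, varies between authors).
#'
#' @export
motif_residue_sets <- function() {
  list(
    aromatic = c("F", "W", "Y"),
    hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C")
  )
}

#' Assemble a peptide panel
#'
#' @param id Peptide identifiers (gene-isoform syntax, e.g. `"FLP-34-1"`).
#' @param sequence One-letter amino-acid strings, N- to C-terminus.
#' @param amidated Logical; carries a C-terminal amide.
#' @param species Species label.
#' @return Tibble with one row per peptide.
#' @export
peptide_panel <- function(id, sequence, amidated = TRUE, species = "C. elegans") {
  sequence <- toupper(sequence)
  if (anyDuplicated(id)) stop("peptide ids must be unique within a panel")
  bad <- !grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"), sequence)
  if (any(bad)) {
    stop("invalid residues in sequence(s): ", paste(id[bad], collapse = ", "))
  }
  tibble::tibble(id = id, sequence = sequence,
                 amidated = rep_len(amidated, length(id)),
                 species = rep_len(species, length(id)))
}

#' Classify peptides by C-terminal consensus motif
#'
#' Tests the last four residues of each amidated peptide, in precedence
#' order: NPF/Y-like (`RxRF/Ya`: Arg at -4 and -2, Phe or Tyr at -1), then
#' FMRFamide-type (`Omega-Psi-R-F-a`: aromatic at -4, hydrophobic at -3),
#' then sNPF-type (`Psi-Psi-R-F-a`). Non-amidated peptides and peptides
#' shorter than four residues are `OTHER`.
#'
#' @param panel A [peptide_panel()] tibble (or any tibble with `id`,
#'   `sequence`, `amidated`).
#' @param aromatic,hydrophobic Residue sets for the Omega and Psi classes;
#'   defaults from [motif_residue_sets()].
#' @return The panel with a `motif` factor column: `NPF_Y_LIKE`,
#'   `FMRFAMIDE`, `SNPF` or `OTHER`.
#' @export
classify_motif <- function(panel,
                           aromatic = motif_residue_sets()$aromatic,
                           hydrophobic = motif_residue_sets()$hydrophobic) {
  stopifnot(all(c("id", "sequence", "amidated") %in% names(panel)))
  bad <- !grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"), panel$sequence)
  if (any(bad)) stop("invalid residues in sequence(s): ",
                     paste(panel$id[bad], collapse = ", "))
  tail4 <- function(s) {
    n <- nchar(s)
    if (n < 4) return(rep(NA_character_, 4))
    substring(s, n - 3:0, n - 3:0)
  }
  cls <- purrr::map2_chr(panel$sequence, panel$amidated, function(s, amid) {
    r <- tail4(s)
    if (!amid || anyNA(r)) return("OTHER")
    if (r[1] == "R" && r[3] == "R" && r[4] %in% c("F", "Y")) return("NPF_Y_LIKE")
    if (r[1] %in% aromatic && r[2] %in% hydrophobic &&
        r[3] == "R" && r[4] == "F") return("FMRFAMIDE")
    if (r[1] %in% hydrophobic && r[2] %in% hydrophobic &&
        r[3] == "R" && r[4] == "F") return("SNPF")
    "OTHER"
  })
  dplyr::mutate(panel, motif = factor(cls, levels = c("NPF_Y_LIKE", "FMRFAMIDE",
                                                      "SNPF", "OTHER")))
}

#' Lesk property category per residue
#'
#' Fixed map used to annotate alignments: small nonpolar (AGST),
#' hydrophobic (CVILPFYMW), polar (NQH), negatively charged (DE),
#' positively charged (KR).
#'
#' @param residues Character vector of one-letter residues.
#' @return Character vector of category labels.
#' @export
lesk_category <- function(residues) {
  map <- c(
    stats::setNames(rep("small_nonpolar", 4), c("A", "G", "S", "T")),
    stats::setNames(rep("hydrophobic", 9), c("C", "V", "I", "L", "P", "F", "Y", "M", "W")),
    stats::setNames(rep("polar", 3), c("N", "Q", "H")),
    stats::setNames(rep("negative", 2), c("D", "E")),
    stats::setNames(rep("positive", 2), c("K", "R"))
  )
  unname(map[residues])
}

#' Right-anchor a peptide panel at the amidated C-terminus
#'
#' Pads every sequence on the N-terminal side with `pad` so all rows end at
#' the same column, the convention for displaying RFamide family alignments.
#'
#' @param panel A [peptide_panel()] tibble.
#' @param pad Padding character (single character).
#' @param annotate Also return long-format per-residue Lesk categories.
#' @return Tibble with `id`, `aligned` (padded string) and `width`; when
#'   `annotate = TRUE`, attribute `"residues"` holds a long tibble
#'   (`id`, `column`, `residue`, `lesk`).
#' @export
align_cterm <- function(panel, pad = "-", annotate = FALSE) {
  if (nrow(panel) == 0) stop("empty peptide panel")
  stopifnot(nchar(pad) == 1)
  width <- max(nchar(panel$sequence))
  aligned <- stringr::str_pad(panel$sequence, width, side = "left", pad = pad)
  out <- tibble::tibble(id = panel$id, aligned = aligned, width = width)
  if (annotate) {
    res <- tidyr::expand_grid(id = panel$id, column = seq_len(width)) |>
      dplyr::mutate(
        residue = stringr::str_sub(aligned[match(.data$id, panel$id)],
                                   .data$column, .data$column),
        lesk = ifelse(.data$residue == pad, NA_character_,
                      lesk_category(.data$residue))
      )
    attr(out, "residues") <- res
  }
  out
}

#' Penultimate arginine to alanine control peptides
#'
#' RFamide receptor activation depends on the conserved arginine at position
#' -2; swapping it for alanine yields a negative-control peptide. The mutant
#' id is suffixed with the substitution in standard notation, e.g.
#' `"[R6A]"` for an Arg at (1-based) position 6.
#'
#' @param panel A [peptide_panel()] tibble; every peptide must carry Arg at
#'   position -2.
#' @return Panel of mutant peptides.
#' @export
arg_to_ala <- function(panel) {
  n <- nchar(panel$sequence)
  pen <- substring(panel$sequence, n - 1, n - 1)
  if (any(pen != "R")) {
    stop("peptide(s) lack the conserved penultimate arginine: ",
         paste(panel$id[pen != "R"], collapse = ", "))
  }
  mutant <- panel
  substring(mutant$sequence, n - 1, n - 1) <- "A"
  mutant$id <- paste0(panel$id, "[R", n - 1, "A]")
  mutant
}
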