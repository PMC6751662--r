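# Fixture truths and independent oracles shared across test files.

# One receptor, one pair per grade (including an asterisk case) with
# well-separated window fractions; window 10x, full screen concentrations.
grade_fixture_truth <- function() example_screen_truth()

grade_fixture_expected <- function() {
  tibble::tribble(
    ~peptide,   ~grade, ~asterisk,
    "pep_v",    "v",    FALSE,
    "pep_iv",   "iv",   FALSE,
    "pep_iii",  "iii",  FALSE,
    "pep_ast",  "iii",  TRUE,
    "pep_ii",   "ii",   FALSE,
    "pep_i",    "i",    FALSE,
    "pep_none", "none", FALSE
  )
}

fixture_panel_spec <- function() {
  tibble::tibble(receptor = "R1", species = "C. elegans", pathway = "Gq_IP")
}

# Independent brute-force transcription of the verbal grading scheme,
# written as literal nested branches (deliberately not sharing code with
# grade_pair). Returns list(grade, asterisk) for scalar inputs.
oracle_grade <- function(active_low, active_high, frac_low, frac_high,
                         full = 0.8, mid = 0.35, delta = 0.10) {
  if (!active_low && !active_high) {
    g <- "none"
  } else if (active_low) {
    if (frac_low >= full) {
      g <- "v"
    } else if (active_high && frac_high >= full) {
      g <- "iv"
    } else {
      g <- "iii"
    }
  } else {
    if (frac_high >= mid) g <- "ii" else g <- "i"
  }
  ast <- FALSE
  if (active_low && active_high) {
    if (abs(frac_high - frac_low) <= delta && frac_high < full) ast <- TRUE
  }
  list(grade = g, asterisk = ast)
}

# Closed-form two-concentration profile of a noise-free agonist on a
# stimulatory window: emulates the full calling chain without simulation.
closed_form_profile <- function(ec50, emax, window, fold_max,
                                conc_low = 1e-7, conc_high = 1e-5, hill = 1,
                                thresholds = call_thresholds()) {
  occ <- function(c) c^hill / (c^hill + ec50^hill)
  fold <- function(c) 1 + (window - 1) * emax * occ(c)
  frac <- function(c) (fold(c) - 1) / (fold_max - 1)
  list(
    active_low = fold(conc_low) >= thresholds$fold_threshold & emax > 0,
    active_high = fold(conc_high) >= thresholds$fold_threshold & emax > 0,
    frac_low = frac(conc_low),
    frac_high = frac(conc_high)
  )
}

# Independent regular-expression oracle for C-terminal motif classes.
regex_motif_oracle <- function(sequence, amidated) {
  if (!amidated || nchar(sequence) < 4) return("OTHER")
  if (grepl("R[A-Z]R[FY]$", sequence)) return("NPF_Y_LIKE")
  if (grepl("[FWY][AVLIMFWC]RF$", sequence)) return("FMRFAMIDE")
  if (grepl("[AVLIMFWC][AVLIMFWC]RF$", sequence)) return("SNPF")
  "OTHER"
}

random_amidated_panel <- function(n, seed) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  # bias the tail toward motif-relevant residues so all classes are hit
  tail_pool <- c(aa, "R", "R", "F", "F", "Y", "W", "L", "A", "M")
  seqs <- vapply(seq_len(n), function(i) {
    len <- sample(4:12, 1)
    paste0(paste(sample(aa, len - 4, replace = TRUE), collapse = ""),
           paste(sample(tail_pool, 4, replace = TRUE), collapse = ""))
  }, character(1))
  peptide_panel(id = paste0("pep", seq_len(n)), sequence = seqs)
}

# Random interaction matrix for candidate-inference equivalence checks.
random_matrix <- function(n_pep, n_rec, seed) {
  set.seed(seed)
  grid <- tidyr::expand_grid(peptide = paste0("P", seq_len(n_pep)),
                             receptor = paste0("R", seq_len(n_rec)))
  grid$grade <- factor(sample(c("none", "i", "ii", "iii", "iv", "v"),
                              nrow(grid), replace = TRUE,
                              prob = c(0.45, 0.11, 0.11, 0.11, 0.11, 0.11)),
                       levels = c("none", "i", "ii", "iii", "iv", "v"),
                       ordered = TRUE)
  grid$asterisk <- grid$grade != "none" & stats::runif(nrow(grid)) < 0.1
  grid$peptide <- factor(grid$peptide, levels = unique(grid$peptide))
  grid$receptor <- factor(grid$receptor, levels = unique(grid$receptor))
  structure(grid, class = c("interaction_matrix", class(grid)))
}

# Exhaustive enumeration oracle for infer_candidates (no shared code).
brute_force_candidates <- function(matrix, target, rescuers, min_grade = "i",
                                   non_rescuers = character(),
                                   exclude_non_rescuers = FALSE) {
  lv <- c("none", "i", "ii", "iii", "iv", "v")
  need <- match(min_grade, lv)
  out <- character()
  for (p in unique(as.character(matrix$peptide))) {
    ok <- TRUE
    for (r in c(target, rescuers)) {
      g <- as.character(matrix$grade[matrix$peptide == p & matrix$receptor == r])
      if (match(g, lv) < need) ok <- FALSE
    }
    if (ok && exclude_non_rescuers && length(non_rescuers) > 0) {
      all_nr <- TRUE
      for (r in non_rescuers) {
        g <- as.character(matrix$grade[matrix$peptide == p & matrix$receptor == r])
        if (match(g, lv) < need) all_nr <- FALSE
      }
      if (all_nr) ok <- FALSE
    }
    if (ok) out <- c(out, p)
  }
  sort(out)
}
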