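#' Default activation thresholds and grade cutpoints
#'
#' `fold_threshold`: minimal fold-of-basal counting as receptor activation
#' (inclusive). `inhibition_threshold`: minimal fractional inhibition of the
#' forskolin-stimulated cAMP signal (0.2 = 20 percent, i.e. fold-of-forskolin
#' at or below 0.8). `full`, `mid`, `delta`: grade cutpoints on the
#' fraction-of-window scale -- at or above `full` counts as full receptor
#' activation, `mid` separates just-above-threshold from roughly
#' half-maximal 10 uM responses, and `delta` is the equality band for the
#' partial-agonist (asterisk) flag. `alpha`: significance level for the
#' Dunnett-adjusted comparisons against the control.
#'
#' @export
call_thresholds <- function(fold_threshold = 2.0,
                            inhibition_threshold = 0.2,
                            full = 0.8,
                            mid = 0.35,
                            delta = 0.10,
                            alpha = 0.05) {
  stopifnot(fold_threshold > 1, inhibition_threshold > 0, inhibition_threshold < 1,
            full > mid, mid > 0, delta >= 0, alpha > 0, alpha < 1)
  list(fold_threshold = fold_threshold,
       inhibition_threshold = inhibition_threshold,
       full = full, mid = mid, delta = delta, alpha = alpha)
}

#' Threshold rule for a normalized response
#'
#' Stimulatory readouts pass at fold-of-basal >= 2 (inclusive); the Gi/o
#' readout passes at fold-of-forskolin <= 0.8, i.e. at least 20 percent
#' inhibition. Vectorized.
#'
#' @param fold Normalized response (fold of basal or fold of forskolin).
#' @param pathway Pathway tag per element.
#' @param thresholds A [call_thresholds()] list.
#' @return Logical vector.
#' @export
above_threshold <- function(fold, pathway, thresholds = call_thresholds()) {
  ifelse(pathway %in% inhibitory_pathways(),
         fold <= 1 - thresholds$inhibition_threshold,
         fold >= thresholds$fold_threshold)
}

#' Per-condition activation significance (one-way ANOVA + Dunnett)
#'
#' Within each receptor x pathway stratum, an one-way ANOVA is fit over all
#' conditions (peptide x concentration plus the control) on per-well
#' normalized folds, followed by Dunnett's many-to-one comparisons of each
#' condition against the control. Requires at least two wells per condition
#' for a variance estimate.
#'
#' @param folds Output of [normalize_folds()].
#' @param alpha Significance level for the adjusted p-values.
#' @return Tibble per receptor x pathway x peptide x concentration with
#'   `p_adj` (Dunnett-adjusted) and `significant`.
#' @export
test_activation <- function(folds, alpha = 0.05) {
  folds |>
    dplyr::group_by(.data$receptor, .data$pathway) |>
    dplyr::group_modify(function(df, key) {
      ctrl <- control_tag_for(key$pathway)
      df$cond <- ifelse(df$peptide == ctrl, ".control",
                        paste0(df$peptide, "@", format(df$conc_M, scientific = TRUE)))
      # drop the other control (buffer wells on the Gi/o readout measure a
      # different baseline and are not part of this comparison family)
      df <- df[df$peptide == ctrl | !df$is_control, , drop = FALSE]
      counts <- table(df$cond)
      if (any(counts < 2)) stop("condition(s) with a single well in stratum ",
                                key$receptor, " / ", key$pathway,
                                ": no variance estimate")
      df$cond <- stats::relevel(factor(df$cond), ref = ".control")
      fit <- stats::aov(fold ~ cond, data = df)
      mse <- stats::deviance(fit) / stats::df.residual(fit)
      cmeans <- tapply(df$fold, df$cond, mean)
      if (!is.finite(mse) || mse < 1e-20 * max(cmeans)^2) {
        # degenerate zero-variance data (noise-free simulation): any exact
        # departure from the control mean counts as significant
        lab <- setdiff(names(cmeans), ".control")
        ps <- ifelse(abs(cmeans[lab] - cmeans[[".control"]]) >
                       1e-9 * abs(cmeans[[".control"]]), 0, 1)
      } else {
        glht <- multcomp::glht(fit, linfct = multcomp::mcp(cond = "Dunnett"))
        ps <- summary(glht)$test$pvalues
        lab <- sub(" - \\.control$", "", names(coef(glht)))
      }
      df |>
        dplyr::filter(.data$cond != ".control") |>
        dplyr::distinct(.data$peptide, .data$conc_M, .data$cond) |>
        dplyr::mutate(p_adj = as.numeric(ps[match(as.character(.data$cond), lab)]),
                      significant = .data$p_adj < alpha) |>
        dplyr::select(-"cond")
    }) |>
    dplyr::ungroup()
}

#' Maximal receptor signal defining the activation window
#'
#' Nematode receptors (`species != "human"`): the strongest response any
#' peptide elicits at any concentration on the designated pathway. Human
#' receptors: the response to the declared endogenous agonist at the top
#' concentration.
#'
#' @param summary A [fold_summary()] tibble.
#' @param panel_spec Tibble per receptor: `receptor`, `species`, `pathway`
#'   (designated readout), and `endogenous_agonist` (required for human
#'   receptors).
#' @return Tibble per receptor with `fold_max` (NA when no peptide responds).
#' @export
receptor_max <- function(summary, panel_spec) {
  stopifnot(all(c("receptor", "species", "pathway") %in% names(panel_spec)))
  purrr::pmap_dfr(
    panel_spec[intersect(c("receptor", "species", "pathway", "endogenous_agonist"),
                         names(panel_spec))],
    function(receptor, species, pathway, endogenous_agonist = NA) {
      rows <- summary[summary$receptor == receptor & summary$pathway == pathway &
                        !summary$peptide %in% c("buffer", "forskolin"), , drop = FALSE]
      if (identical(species, "human")) {
        if (is.na(endogenous_agonist)) {
          stop("human receptor ", receptor, " lacks a declared endogenous agonist")
        }
        rows <- rows[rows$peptide == endogenous_agonist, , drop = FALSE]
        rows <- rows[rows$conc_M == max(rows$conc_M), , drop = FALSE]
      }
      if (nrow(rows) == 0) {
        return(tibble::tibble(receptor = receptor, pathway = pathway,
                              fold_max = NA_real_))
      }
      strongest <- if (pathway %in% inhibitory_pathways()) {
        min(rows$fold_mean)
      } else {
        max(rows$fold_mean)
      }
      tibble::tibble(receptor = receptor, pathway = pathway, fold_max = strongest)
    }
  )
}

#' Fraction of the receptor window
#'
#' Stimulatory readouts: `(fold - 1) / (fold_max - 1)`; Gi/o readout:
#' `(1 - fold) / (1 - fold_max)` so 0 is basal and 1 the receptor maximum in
#' both conventions.
#'
#' @keywords internal
window_fraction <- function(fold, fold_max, pathway) {
  ifelse(pathway %in% inhibitory_pathways(),
         (1 - fold) / (1 - fold_max),
         (fold - 1) / (fold_max - 1))
}

grade_levels <- function() c("none", "i", "ii", "iii", "iv", "v")

#' Grade a two-concentration activation profile
#'
#' Mechanical five-grade scheme over low (0.1 uM) and high (10 uM) screen
#' responses expressed as fractions of the receptor window:
#' `none` -- neither concentration active; `i` -- active only at 10 uM,
#' below the `mid` cutpoint (just above threshold); `ii` -- active only at
#' 10 uM, at or above `mid` (roughly half-maximal and beyond); `iii` --
#' active already at 0.1 uM but submaximal at 10 uM; `iv` -- partial
#' activation at 0.1 uM and full activation at 10 uM; `v` -- full receptor
#' activation already at 0.1 uM. The asterisk flags high-affinity partial
#' agonism: both concentrations active with equal (within `delta`) but
#' submaximal responses. Vectorized over all arguments.
#'
#' @param active_low,active_high Logical: activation call (threshold AND
#'   significance) at the low / high screening concentration.
#' @param frac_low,frac_high Fraction of the receptor window at each
#'   concentration (0 = basal, 1 = receptor maximum).
#' @param thresholds A [call_thresholds()] list (uses `full`, `mid`, `delta`).
#' @return Tibble with `grade` (ordered factor none < i < ... < v) and
#'   `asterisk`.
#' @export
grade_pair <- function(active_low, active_high, frac_low, frac_high,
                       thresholds = call_thresholds()) {
  frac_low <- ifelse(active_low | active_high, frac_low, NA_real_)
  chk <- c(frac_low[!is.na(frac_low)], frac_high[!is.na(frac_high) &
                                                   (active_low | active_high)])
  if (any(chk < -0.2 | chk > 1.5)) {
    stop("window fraction outside [-0.2, 1.5]: normalization fault")
  }
  full <- thresholds$full; mid <- thresholds$mid; delta <- thresholds$delta
  grade <- dplyr::case_when(
    !active_low & !active_high ~ "none",
    active_low & frac_low >= full ~ "v",
    active_low & active_high & frac_high >= full ~ "iv",
    active_low ~ "iii",
    frac_high >= mid ~ "ii",
    .default = "i"
  )
  asterisk <- active_low & active_high &
    abs(frac_high - frac_low) <= delta & frac_high < full
  tibble::tibble(
    grade = factor(grade, levels = grade_levels(), ordered = TRUE),
    asterisk = dplyr::coalesce(asterisk, FALSE)
  )
}

#' Call per-pair activation from normalized plate data
#'
#' Runs the full calling chain for the designated readout pathway of each
#' receptor: condition summaries, receptor window, threshold rule,
#' Dunnett-adjusted significance, and the two-concentration grading with
#' partial-agonist flagging. A condition is "active" when it passes the
#' threshold AND differs significantly from the control.
#'
#' @param folds Output of [normalize_folds()].
#' @param panel_spec Receptor spec as in [receptor_max()].
#' @param conc_low,conc_high The two screening concentrations (molar).
#' @param thresholds A [call_thresholds()] list.
#' @return Tibble per receptor x peptide: activity flags, window fractions,
#'   `grade`, `asterisk`.
#' @export
call_activation <- function(folds, panel_spec,
                            conc_low = 1e-7, conc_high = 1e-5,
                            thresholds = call_thresholds()) {
  folds <- dplyr::semi_join(folds, panel_spec, by = c("receptor", "pathway"))
  summ <- fold_summary(folds)
  sig <- test_activation(folds, alpha = thresholds$alpha)
  rmax <- receptor_max(summ, panel_spec)
  calls <- summ |>
    dplyr::filter(!.data$peptide %in% c("buffer", "forskolin"),
                  .data$conc_M %in% c(conc_low, conc_high)) |>
    dplyr::left_join(sig, by = c("receptor", "pathway", "peptide", "conc_M")) |>
    dplyr::left_join(rmax, by = c("receptor", "pathway")) |>
    dplyr::mutate(
      passes = above_threshold(.data$fold_mean, .data$pathway, thresholds),
      active = .data$passes & dplyr::coalesce(.data$significant, FALSE),
      frac = dplyr::if_else(
        is.na(.data$fold_max), NA_real_,
        window_fraction(.data$fold_mean, .data$fold_max, .data$pathway)
      ),
      which = dplyr::if_else(.data$conc_M == conc_low, "low", "high")
    ) |>
    dplyr::select("receptor", "pathway", "peptide", "which", "active", "frac") |>
    tidyr::pivot_wider(names_from = "which", values_from = c("active", "frac"))
  # a receptor where nothing responds has no window; its rows grade none
  undef <- is.na(calls$frac_low) | is.na(calls$frac_high)
  calls$active_low[undef] <- FALSE
  calls$active_high[undef] <- FALSE
  calls$frac_low[undef] <- 0
  calls$frac_high[undef] <- 0
  dplyr::bind_cols(
    calls,
    grade_pair(calls$active_low, calls$active_high,
               calls$frac_low, calls$frac_high, thresholds)
  )
}

#' Build the peptide x receptor interaction matrix
#'
#' Completes the calls over a declared peptide x receptor panel (missing
#' combinations grade `none`), fixes a deterministic ordering, and wraps the
#' result for serialization and plotting.
#'
#' @param calls Output of [call_activation()].
#' @param peptides,receptors Ordered panels; default to the values present.
#' @return An `interaction_matrix`: a tibble (peptide x receptor grid) with
#'   class attributes.
#' @export
build_interaction_matrix <- function(calls,
                                     peptides = unique(calls$peptide),
                                     receptors = unique(calls$receptor)) {
  missing_r <- setdiff(receptors, calls$receptor)
  if (length(missing_r) > 0) {
    stop("no calls for receptor(s): ", paste(missing_r, collapse = ", "))
  }
  grid <- tidyr::expand_grid(peptide = peptides, receptor = receptors) |>
    dplyr::left_join(calls, by = c("peptide", "receptor")) |>
    dplyr::mutate(
      grade = dplyr::coalesce(.data$grade,
                              factor("none", levels = grade_levels(), ordered = TRUE)),
      asterisk = dplyr::coalesce(.data$asterisk, FALSE),
      peptide = factor(.data$peptide, levels = peptides),
      receptor = factor(.data$receptor, levels = receptors)
    ) |>
    dplyr::arrange(.data$peptide, .data$receptor)
  structure(grid, class = c("interaction_matrix", class(grid)))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("<interaction_matrix> ", dplyr::n_distinct(x$peptide), " peptide(s) x ",
      dplyr::n_distinct(x$receptor), " receptor(s)\n", sep = "")
  wide <- x |>
    dplyr::mutate(cell = paste0(as.character(.data$grade),
                                ifelse(.data$asterisk, "*", ""))) |>
    dplyr::select("peptide", "receptor", "cell") |>
    tidyr::pivot_wider(names_from = "receptor", values_from = "cell")
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' G-protein coupling preference of each receptor
#'
#' A pathway counts as activated when at least one peptide condition shifts
#' the normalized second messenger significantly away from its control (two-
#' way ANOVA over pathway and stimulation, Bonferroni-adjusted cell
#' contrasts across the whole family) AND passes the activation threshold.
#' Among activated pathways the one with the strongest signal is primary
#' (highest fold of basal; for the Gi/o readout the fold-suppression of the
#' forskolin signal, `1 / fold`, is used as the comparable strength), the
#' rest secondary.
#'
#' @param folds Output of [normalize_folds()] covering one or more pathways
#'   per receptor.
#' @param alpha Family significance level.
#' @param thresholds A [call_thresholds()] list.
#' @return Tibble per receptor x pathway with `status` in
#'   `inactive`/`secondary`/`primary` and the supporting `strength`.
#' @export
coupling_profile <- function(folds, alpha = 0.05, thresholds = call_thresholds()) {
  if (nrow(folds) == 0) stop("no pathway measurements supplied")
  folds |>
    dplyr::group_by(.data$receptor) |>
    dplyr::group_modify(function(df, key) {
      df$stimulation <- ifelse(df$is_control, ".control",
                               paste0(df$peptide, "@",
                                      format(df$conc_M, scientific = TRUE)))
      df$pathway_f <- factor(df$pathway)
      df$stimulation <- stats::relevel(factor(df$stimulation), ref = ".control")
      fit <- if (nlevels(df$pathway_f) > 1) {
        stats::aov(fold ~ pathway_f * stimulation, data = df)
      } else {
        stats::aov(fold ~ stimulation, data = df)
      }
      em <- if (nlevels(df$pathway_f) > 1) {
        emmeans::emmeans(fit, ~ stimulation | pathway_f, data = df,
                         nesting = NULL)
      } else {
        emmeans::emmeans(fit, ~ stimulation, data = df, nesting = NULL)
      }
      ctr <- summary(emmeans::contrast(em, "trt.vs.ctrl", ref = ".control",
                                       adjust = "none"))
      ctr$p_adj <- pmin(1, ctr$p.value * nrow(ctr))  # Bonferroni, whole family
      if (!"pathway_f" %in% names(ctr)) ctr$pathway_f <- levels(df$pathway_f)[1]
      names(ctr)[names(ctr) == "pathway_f"] <- "pathway"
      per_cond <- df[!df$is_control, , drop = FALSE] |>
        dplyr::summarise(fold = mean(.data$fold),
                         .by = c("pathway", "stimulation", "experiment")) |>
        dplyr::summarise(fold_mean = mean(.data$fold),
                         .by = c("pathway", "stimulation")) |>
        dplyr::mutate(stimulation = as.character(.data$stimulation),
                      pathway = as.character(.data$pathway))
      ctr <- dplyr::left_join(
        tibble::as_tibble(ctr[c("contrast", "pathway", "p_adj")]) |>
          dplyr::mutate(
            stimulation = sub("^\\((.*)\\)$", "\\1",
                              sub(" - \\.?control$", "",
                                  sub("^\\(?\\.?control\\)? - ", "",
                                      as.character(.data$contrast)))),
            pathway = as.character(.data$pathway)),
        per_cond, by = c("pathway", "stimulation")
      )
      path_status <- ctr |>
        dplyr::mutate(
          hit = !is.na(.data$p_adj) & .data$p_adj < alpha &
            !is.na(.data$fold_mean) &
            above_threshold(.data$fold_mean, .data$pathway, thresholds),
          strength = ifelse(.data$pathway %in% inhibitory_pathways(),
                            1 / .data$fold_mean, .data$fold_mean)
        ) |>
        dplyr::summarise(active = any(.data$hit),
                         strength = max(.data$strength[.data$hit], -Inf),
                         .by = "pathway")
      path_status$status <- ifelse(path_status$active, "secondary", "inactive")
      if (any(path_status$active)) {
        path_status$status[which.max(ifelse(path_status$active,
                                            path_status$strength, -Inf))] <- "primary"
      }
      path_status$strength[!path_status$active] <- NA_real_
      path_status[c("pathway", "status", "strength")]
    }) |>
    dplyr::ungroup()
}
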