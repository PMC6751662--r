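#' Fit a four-parameter logistic concentration-response curve
#'
#' Nonlinear least squares on
#' `response = bottom + (top - bottom) / (1 + 10^(hill * (log10(EC50) - log10(c))))`,
#' fit on the log10-concentration scale with Levenberg-Marquardt steps and
#' multi-start initialization: bottom/top from the response extremes, a
#' log10-EC50 grid spanning the observed concentration range, and hill
#' starts at 0.5, 1 and 2 (mirrored for descending curves). The best
#' converged start by residual sum of squares is kept. Standard errors come
#' from the Jacobian-based covariance.
#'
#' @param points Tibble with `conc_M` (molar, > 0) and `response` columns;
#'   replicate rows per concentration are fine. Rows with nonpositive
#'   concentration are dropped.
#' @param fix_hill Fix the hill slope to a value (e.g. `1` for normal
#'   steepness) instead of fitting it; `NULL` (default) fits it freely.
#' @return Object of class `fit_4pl` with elements `estimate` (named vector:
#'   bottom, top, log10_ec50, hill), `se`, `vcov`, `sigma`, `converged`,
#'   `n`, `data`. `ec50()` is `10^log10_ec50`. The fit is flagged
#'   non-converged when no start succeeds or the response window is not
#'   identifiable (flat data).
#' @export
fit_4pl <- function(points, fix_hill = NULL) {
  stopifnot(all(c("conc_M", "response") %in% names(points)))
  pts <- dplyr::filter(tibble::as_tibble(points), .data$conc_M > 0,
                       is.finite(.data$response))
  if (dplyr::n_distinct(pts$conc_M) < 4) {
    stop("need at least 4 distinct positive concentrations")
  }
  df <- tibble::tibble(logc = log10(pts$conc_M), y = pts$response)
  ymin <- min(df$y); ymax <- max(df$y); span <- ymax - ymin
  med <- stats::median(df$y)
  # direction of the curve: correlation of response with log concentration
  # (flat data defaults to ascending; the window check flags it anyway)
  ascending <- stats::sd(df$y) == 0 ||
    isTRUE(suppressWarnings(stats::cor(df$logc, df$y)) >= 0)
  lec_grid <- seq(min(df$logc), max(df$logc), length.out = 5)
  hill_grid <- if (is.null(fix_hill)) c(0.5, 1, 2) else fix_hill
  starts <- tidyr::expand_grid(lec = lec_grid, h = hill_grid)

  fits <- purrr::pmap(starts, function(lec, h) {
    start <- if (ascending) {
      list(bottom = ymin, top = ymax, lec50 = lec, hill = h)
    } else {
      list(bottom = ymax, top = ymin, lec50 = lec, hill = h)
    }
    form <- y ~ bottom + (top - bottom) / (1 + 10^(hill * (lec50 - logc)))
    if (!is.null(fix_hill)) {
      form <- stats::as.formula(
        sprintf("y ~ bottom + (top - bottom) / (1 + 10^(%g * (lec50 - logc)))",
                fix_hill))
      start$hill <- NULL
    }
    tryCatch(
      minpack.lm::nlsLM(form, data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) {
    return(new_fit_4pl(NULL, df, fix_hill, converged = FALSE))
  }
  best <- fits[[which.min(purrr::map_dbl(fits, stats::deviance))]]
  new_fit_4pl(best, df, fix_hill, converged = TRUE)
}

new_fit_4pl <- function(fit, df, fix_hill, converged) {
  if (is.null(fit)) {
    est <- c(bottom = NA_real_, top = NA_real_, log10_ec50 = NA_real_,
             hill = if (is.null(fix_hill)) NA_real_ else fix_hill)
    return(structure(list(estimate = est, se = est * NA, vcov = NULL,
                          sigma = NA_real_, converged = FALSE,
                          n = nrow(df), data = df, fix_hill = fix_hill),
                     class = "fit_4pl"))
  }
  cf <- stats::coef(fit)
  est <- c(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
           log10_ec50 = unname(cf["lec50"]),
           hill = if (is.null(fix_hill)) unname(cf["hill"]) else fix_hill)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se <- c(bottom = NA_real_, top = NA_real_, log10_ec50 = NA_real_, hill = NA_real_)
  if (!is.null(vc)) {
    d <- sqrt(pmax(diag(vc), 0))
    se["bottom"] <- d["bottom"]; se["top"] <- d["top"]; se["log10_ec50"] <- d["lec50"]
    if (is.null(fix_hill)) se["hill"] <- d["hill"] else se["hill"] <- 0
  }
  sigma <- sqrt(stats::deviance(fit) / max(1, stats::df.residual(fit)))
  window <- abs(est["top"] - est["bottom"])
  scale <- max(abs(df$y), 1e-300)
  # identifiability: a window indistinguishable from zero (relative to the
  # data scale or its own standard error) leaves EC50 undefined
  se_window <- if (!is.null(vc)) {
    sqrt(max(0, vc["bottom", "bottom"] + vc["top", "top"] -
               2 * vc["bottom", "top"]))
  } else {
    Inf
  }
  identifiable <- is.finite(window) && window > 1e-6 * scale &&
    (window > 2 * se_window || !is.finite(se_window))
  structure(list(estimate = est, se = se, vcov = vc, sigma = sigma,
                 converged = converged && identifiable,
                 n = nrow(df), data = df, fix_hill = fix_hill),
            class = "fit_4pl")
}

#' Fitted EC50 in molar units
#' @param fit A `fit_4pl` object.
#' @export
ec50 <- function(fit) {
  stopifnot(inherits(fit, "fit_4pl"))
  unname(10^fit$estimate["log10_ec50"])
}

#' @export
print.fit_4pl <- function(x, ...) {
  cat("<fit_4pl> ", if (x$converged) "converged" else "NOT converged",
      ", n = ", x$n, "\n", sep = "")
  if (x$converged) {
    cat(sprintf("  EC50 = %.3g M (log10 %.3f +/- %.3f), hill = %.3g\n",
                ec50(x), x$estimate["log10_ec50"], x$se["log10_ec50"],
                x$estimate["hill"]))
    cat(sprintf("  bottom = %.3g, top = %.3g, sigma = %.3g\n",
                x$estimate["bottom"], x$estimate["top"], x$sigma))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a 4PL fit into one row per parameter
#' @param x A `fit_4pl` object.
#' @param ... Unused.
#' @export
tidy.fit_4pl <- function(x, ...) {
  tibble::tibble(term = names(x$estimate),
                 estimate = unname(x$estimate),
                 std.error = unname(x$se))
}

#' One-row fit summary
#' @param x A `fit_4pl` object.
#' @param ... Unused.
#' @export
glance.fit_4pl <- function(x, ...) {
  tibble::tibble(
    ec50 = if (x$converged) ec50(x) else NA_real_,
    log10_ec50_se = unname(x$se["log10_ec50"]),
    hill = unname(x$estimate["hill"]),
    window = unname(abs(x$estimate["top"] - x$estimate["bottom"])),
    sigma = x$sigma, n = x$n, converged = x$converged
  )
}

#' Emax relative to a reference agonist
#'
#' `100 * (top - bottom) / (top_ref - bottom_ref)`, the convention for
#' reporting a ligand's maximal response in percent of the receptor's
#' reference agonist on the same readout.
#'
#' @param fit,reference_fit Converged `fit_4pl` objects from the same
#'   receptor and pathway.
#' @return Percent of the reference response window.
#' @export
normalize_emax <- function(fit, reference_fit) {
  stopifnot(inherits(fit, "fit_4pl"), inherits(reference_fit, "fit_4pl"))
  if (!reference_fit$converged) stop("reference fit did not converge")
  ref_window <- reference_fit$estimate["top"] - reference_fit$estimate["bottom"]
  win <- fit$estimate["top"] - fit$estimate["bottom"]
  if (abs(ref_window) <= 0 || !is.finite(ref_window)) {
    stop("reference response window is not positive")
  }
  # windows on the same readout share a sign; the ratio is direction-free
  unname(100 * win / ref_window)
}

#' Fit concentration-response curves for receptor x peptide pairs
#'
#' Convenience wrapper over [fit_4pl()] operating on normalized folds:
#' extracts the per-well fold values of each requested pair, fits the 4PL,
#' and expresses Emax relative to the pair's reference peptide.
#'
#' @param folds Output of [normalize_folds()].
#' @param pairs Tibble with `receptor`, `peptide`, `pathway` and
#'   `reference_peptide`.
#' @param fix_hill Passed to [fit_4pl()].
#' @return Tibble: one row per pair with `ec50`, `log10_ec50_se`, `hill`,
#'   `emax_pct_reference`, `basal`, `converged`, and the fit objects in a
#'   list column `fit`.
#' @export
fit_dose_response <- function(folds, pairs, fix_hill = NULL) {
  fit_one <- function(receptor, peptide, pathway) {
    pts <- folds |>
      dplyr::filter(.data$receptor == !!receptor, .data$peptide == !!peptide,
                    .data$pathway == !!pathway, .data$conc_M > 0) |>
      dplyr::select(conc_M = "conc_M", response = "fold")
    fit_4pl(pts, fix_hill = fix_hill)
  }
  refs <- dplyr::distinct(pairs, .data$receptor, .data$pathway,
                          peptide = .data$reference_peptide)
  ref_fits <- purrr::pmap(refs, fit_one)
  names(ref_fits) <- paste(refs$receptor, refs$pathway, refs$peptide, sep = "|")
  purrr::pmap_dfr(
    pairs[c("receptor", "peptide", "pathway", "reference_peptide")],
    function(receptor, peptide, pathway, reference_peptide) {
      fit <- fit_one(receptor, peptide, pathway)
      ref <- ref_fits[[paste(receptor, pathway, reference_peptide, sep = "|")]]
      emax_pct <- if (fit$converged && ref$converged) {
        normalize_emax(fit, ref)
      } else {
        NA_real_
      }
      tibble::tibble(
        receptor = receptor, peptide = peptide, pathway = pathway,
        reference_peptide = reference_peptide,
        ec50 = if (fit$converged) ec50(fit) else NA_real_,
        log10_ec50_se = unname(fit$se["log10_ec50"]),
        hill = unname(fit$estimate["hill"]),
        emax_pct_reference = emax_pct,
        basal = unname(fit$estimate["bottom"]),
        converged = fit$converged,
        fit = list(fit)
      )
    }
  )
}

#' EC50 bands implied by the two-concentration screen grades
#'
#' The screen grades coarsely encode potency for full agonists: grades i/ii
#' correspond to an estimated EC50 of 10-100 uM, grade iii to roughly 1 uM
#' (band 0.3-3 uM), grade iv to roughly 0.1 uM (band 30-300 nM), and grade
#' v to below 100 nM.
#'
#' @return Tibble with `grade`, `ec50_min`, `ec50_max` (molar).
#' @export
grade_ec50_bands <- function() {
  tibble::tribble(
    ~grade, ~ec50_min, ~ec50_max,
    "i",    1e-5,      1e-4,
    "ii",   1e-5,      1e-4,
    "iii",  3e-7,      3e-6,
    "iv",   3e-8,      3e-7,
    "v",    0,         1e-7
  )
}

#' Check fitted EC50s against the grade-implied potency bands
#'
#' Joins fits with screen calls and reports, for full agonists, whether the
#' fitted EC50 falls inside the band its grade implies. Partial agonists
#' (asterisk cells) are excluded: the band mapping assumes full agonism.
#'
#' @param fits Output of [fit_dose_response()].
#' @param calls Output of [call_activation()] (or an interaction matrix).
#' @return Tibble per pair with `grade`, `ec50`, `band_min`, `band_max`,
#'   `status` in `consistent` / `inconsistent` / `not_applicable`.
#' @export
grade_band_check <- function(fits, calls) {
  bands <- grade_ec50_bands()
  fits |>
    dplyr::select("receptor", "peptide", "ec50", "converged") |>
    dplyr::left_join(
      dplyr::mutate(calls, grade = as.character(.data$grade))[
        c("receptor", "peptide", "grade", "asterisk")],
      by = c("receptor", "peptide")
    ) |>
    dplyr::left_join(bands, by = "grade") |>
    dplyr::mutate(
      status = dplyr::case_when(
        is.na(.data$grade) | .data$grade == "none" | .data$asterisk |
          !.data$converged ~ "not_applicable",
        .data$ec50 >= .data$ec50_min & .data$ec50 <= .data$ec50_max ~ "consistent",
        .default = "inconsistent"
      )
    ) |>
    dplyr::select("receptor", "peptide", "grade", "asterisk", "ec50",
                  band_min = "ec50_min", band_max = "ec50_max", "status")
}
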