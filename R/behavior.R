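#' Methyl-salicylate avoidance index per plate
#'
#' As conventionally printed: worms on the ethanol sides subtracted from
#' worms on the methyl-salicylate sides, divided by the total worm count.
#' Under `sign_convention = "avoidance_positive"` the sign is flipped so
#' that animals avoiding the repellent score positive. The denominator is
#' the scored count (`n_mesa + n_eoh`) by default; with
#' `include_unscored = TRUE` it is `n_total` (all worms placed).
#'
#' @param counts Tibble with `n_mesa`, `n_eoh` and (if `include_unscored`)
#'   `n_total`.
#' @param sign_convention `"as_printed"` (MeSa minus EOH) or
#'   `"avoidance_positive"` (EOH minus MeSa).
#' @param include_unscored Divide by all placed worms instead of scored.
#' @return Input with an `avoidance_index` column in [-1, 1].
#' @export
avoidance_index <- function(counts,
                            sign_convention = c("as_printed", "avoidance_positive"),
                            include_unscored = FALSE) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(all(counts$n_mesa >= 0), all(counts$n_eoh >= 0))
  if ("n_total" %in% names(counts) &&
      any(counts$n_mesa + counts$n_eoh > counts$n_total)) {
    stop("scored worms exceed n_total")
  }
  denom <- if (include_unscored) counts$n_total else counts$n_mesa + counts$n_eoh
  if (any(denom == 0)) stop("plate with zero scored worms")
  ai <- (counts$n_mesa - counts$n_eoh) / denom
  if (sign_convention == "avoidance_positive") ai <- -ai
  dplyr::mutate(counts, avoidance_index = ai)
}

#' Bordering fraction per plate
#'
#' Fraction of animals within the 2 mm border zone of the bacterial lawn.
#'
#' @param counts Tibble with `n_border` and `n_total`.
#' @return Input with a `bordering_fraction` column in [0, 1].
#' @export
bordering_fraction <- function(counts) {
  stopifnot(all(counts$n_border >= 0))
  if (any(counts$n_border > counts$n_total)) stop("n_border exceeds n_total")
  if (any(counts$n_total == 0)) stop("plate with zero worms")
  dplyr::mutate(counts, bordering_fraction = .data$n_border / .data$n_total)
}

#' Compare per-plate behavioral scores between genotypes
#'
#' The plate is the statistical unit. With more than two genotypes: one-way
#' ANOVA followed by Bonferroni-adjusted pairwise comparisons against the
#' reference genotype (pooled-variance t statistics on the ANOVA mean
#' square). With exactly two genotypes: an unpaired two-sample t-test.
#' Significance stars follow the usual figure convention
#' (`*` p < 0.05, `***` p < 0.001).
#'
#' @param data Tibble with one row per plate.
#' @param value Name of the score column (string), e.g.
#'   `"avoidance_index"`.
#' @param reference Reference genotype the others are compared against.
#' @param method `"auto"` picks the t-test for two groups and
#'   ANOVA + Bonferroni otherwise; either can be forced.
#' @param var_equal For the two-group t-test: pooled variance (`TRUE`,
#'   classical Student test) or Welch (`FALSE`).
#' @return Object of class `group_comparison`: a tibble per genotype with
#'   `mean`, `sd`, `n_plates`, `p_adj` vs the reference (NA for the
#'   reference itself), `significant`, `stars`; test metadata in
#'   attributes.
#' @export
compare_groups <- function(data, value, reference,
                           method = c("auto", "anova_bonferroni", "t_test"),
                           var_equal = TRUE) {
  method <- match.arg(method)
  stopifnot("genotype" %in% names(data), value %in% names(data))
  if (!reference %in% data$genotype) stop("reference genotype not in data")
  v <- data[[value]]
  groups <- sort(unique(data$genotype))
  counts <- table(data$genotype)
  if (any(counts < 2)) {
    stop("genotype(s) with fewer than 2 plates: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  k <- length(groups)
  if (method == "auto") method <- if (k == 2) "t_test" else "anova_bonferroni"
  others <- setdiff(groups, reference)

  if (method == "t_test") {
    if (k != 2) stop("t_test requires exactly two genotypes")
    p <- stats::t.test(v[data$genotype == others],
                       v[data$genotype == reference],
                       var.equal = var_equal)$p.value
    p_adj <- stats::setNames(p, others)
  } else {
    fit <- stats::aov(score ~ genotype,
                      data = tibble::tibble(score = v, genotype = data$genotype))
    mse <- stats::deviance(fit) / stats::df.residual(fit)
    dfree <- stats::df.residual(fit)
    m <- tapply(v, data$genotype, mean)
    n <- tapply(v, data$genotype, length)
    tstat <- (m[others] - m[[reference]]) /
      sqrt(mse * (1 / n[others] + 1 / n[[reference]]))
    p_adj <- stats::setNames(
      pmin(1, 2 * stats::pt(abs(tstat), dfree, lower.tail = FALSE) *
             length(others)),
      others)
  }
  out <- tibble::tibble(
    genotype = groups,
    mean = as.numeric(tapply(v, data$genotype, mean)[groups]),
    sd = as.numeric(tapply(v, data$genotype, stats::sd)[groups]),
    n_plates = as.integer(counts[groups]),
    p_adj = ifelse(groups == reference, NA_real_,
                   as.numeric(p_adj[groups]))
  ) |>
    dplyr::mutate(
      significant = !is.na(.data$p_adj) & .data$p_adj < 0.05,
      stars = dplyr::case_when(
        is.na(.data$p_adj) ~ "",
        .data$p_adj < 0.001 ~ "***",
        .data$p_adj < 0.05 ~ "*",
        .default = "ns"
      )
    )
  structure(out, class = c("group_comparison", class(out)),
            reference = reference, method = method, value = value)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", attr(x, "value"), " by genotype; ",
      attr(x, "method"), " vs reference ", attr(x, "reference"), "\n", sep = "")
  NextMethod()
}
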