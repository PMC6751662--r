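#' Heatmap of an interaction matrix
#'
#' Tile plot of grades (light to dark with increasing potency class),
#' asterisk cells annotated; receptors on the x axis, peptides top to
#' bottom in panel order.
#'
#' @param object An interaction matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interaction_matrix <- function(object, ...) {
  shades <- c(none = "grey95", i = "#d9f0d3", ii = "#a6dba0",
              iii = "#5aae61", iv = "#1b7837", v = "#00441b")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$receptor,
                               y = forcats_rev(.data$peptide),
                               fill = .data$grade)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.4) +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$asterisk, "*", "")),
                       size = 5, vjust = 0.75) +
    ggplot2::scale_fill_manual(values = shades, drop = FALSE, name = "grade") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

# reverse factor levels without importing forcats
forcats_rev <- function(f) factor(f, levels = rev(levels(f)))

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted concentration-response curve over its data
#'
#' @param object A `fit_4pl` object.
#' @param n_grid Points on the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fit_4pl <- function(object, n_grid = 200, ...) {
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$logc, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "log10 concentration (M)", y = "response") +
    ggplot2::theme_classic()
  if (object$converged) {
    e <- object$estimate
    grid <- tibble::tibble(logc = seq(min(df$logc), max(df$logc),
                                      length.out = n_grid))
    grid$y <- e["bottom"] + (e["top"] - e["bottom"]) /
      (1 + 10^(e["hill"] * (e["log10_ec50"] - grid$logc)))
    p <- p + ggplot2::geom_line(data = grid, color = "#1b7837", linewidth = 0.8)
  }
  p
}

#' Per-genotype summary plot of a behavioral comparison
#'
#' Bar of group means with SD error bars and significance stars versus the
#' reference genotype, mirroring the usual figure annotation.
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars,
                                    y = .data$mean + .data$sd),
                       vjust = -0.5) +
    ggplot2::labs(x = NULL, y = attr(object, "value")) +
    ggplot2::theme_classic()
}
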