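#' Plot variance components of a fitted model
#'
#' Bar chart of the REML variance components with +/- 1 SE whiskers.
#'
#' @param object An `ncii_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ncii_fit
#' @export
autoplot.ncii_fit <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = d$term)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$estimate - .data$se, 0),
                   ymax = .data$estimate + .data$se),
      width = 0.25
    ) +
    ggplot2::labs(
      x = NULL, y = "variance component",
      title = sprintf("%s, trait %s", object$model, object$trait)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot GCA effects with significance annotation
#'
#' Bar chart of the general combining-ability BLUPs per parent, faceted by
#' role, starred at the usual significance levels.
#'
#' @param ca A `ca_tables` object from [combining_ability_tables()], or
#'   the long GCA tibble from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_gca <- function(ca) {
  g <- if (inherits(ca, "ca_tables")) ca$gca else ca
  ggplot2::ggplot(g, ggplot2::aes(x = .data$parent, y = .data$blup)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$stars,
                   vjust = ifelse(.data$blup >= 0, -0.3, 1.2)),
      size = 3
    ) +
    ggplot2::facet_wrap(~role, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "GCA effect (BLUP)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the distribution of mid- and best-parent heterosis
#'
#' Overlaid density of MPH and BPH percentages, faceted by year when a
#' `year` column is present.
#'
#' @param het A heterosis table (from [build_heterosis_table()] or
#'   `run_pipeline()$heterosis`).
#' @return A ggplot object.
#' @export
plot_heterosis <- function(het) {
  long <- tidyr::pivot_longer(het, c("mph", "bph"), names_to = "type",
                              values_to = "pct")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pct,
                                          fill = .data$type)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "heterosis (%)", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
  if ("year" %in% names(het)) p <- p + ggplot2::facet_wrap(~year)
  p
}

#' Heatmap of a trait-by-trait correlation matrix
#'
#' @param mat A list from [trait_cor_matrix()].
#' @return A ggplot object.
#' @export
plot_cor_matrix <- function(mat) {
  rho <- mat$rho
  d <- tidyr::expand_grid(row = rownames(rho), col = colnames(rho))
  d$rho <- rho[cbind(d$row, d$col)]
  d$stars <- p_stars(mat$p[cbind(d$row, d$col)], ns = "")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "indianred",
                                  high = "steelblue", mid = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme_minimal()
}
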