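# ggplot2 visualisations for the main result types.

#' Volcano plot of a `volcano_result`
#'
#' @param object A [volcano()] result.
#' @param ... Unused.
#' @return A ggplot: log2 fold change vs -log10 adjusted p, significantly
#'   dysregulated compounds highlighted, threshold guides drawn.
#' @exportS3Method ggplot2::autoplot
autoplot.volcano_result <- function(object, ...) {
  tab <- object$table
  tab <- tab[is.finite(tab$log2_fc) & !is.na(tab$p_adjusted), ]
  ggplot2::ggplot(
    tab,
    ggplot2::aes(
      x = .data$log2_fc, y = -log10(.data$p_adjusted),
      colour = .data$significant
    )
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(
      xintercept = c(-1, 1) * log2(object$fc_threshold),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::geom_hline(
      yintercept = -log10(object$alpha),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "grey60"),
      name = "dysregulated"
    ) +
    ggplot2::labs(
      x = "log2 fold change (stress / control)",
      y = "-log10 adjusted p-value"
    ) +
    ggplot2::theme_minimal()
}

#' Score plot of a `feature_pca`
#'
#' @param object A [pca_features()] result.
#' @param ... Unused.
#' @return A ggplot of the first two principal components, coloured by
#'   sample class, axes annotated with explained variance.
#' @exportS3Method ggplot2::autoplot
autoplot.feature_pca <- function(object, ...) {
  sc <- object$scores
  ev <- object$explained_variance
  lab <- function(k) {
    sprintf("PC%d (%.1f%%)", k, 100 * ev[k])
  }
  ggplot2::ggplot(
    sc, ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$class)
  ) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = lab(1), y = if (length(ev) > 1) lab(2) else "PC2") +
    ggplot2::theme_minimal()
}

#' Plot one spectrum (optionally head-to-tail against a second)
#'
#' @param spectrum One-row spectra tibble.
#' @param reference Optional one-row spectra tibble drawn downwards for
#'   head-to-tail comparison.
#' @return A ggplot of intensity sticks over m/z.
#' @export
plot_spectrum <- function(spectrum, reference = NULL) {
  stopifnot(nrow(spectrum) == 1L)
  p1 <- spectrum$peaks[[1]]
  p1$which <- spectrum$id
  dat <- p1
  if (!is.null(reference)) {
    stopifnot(nrow(reference) == 1L)
    p2 <- reference$peaks[[1]]
    p2$intensity <- -p2$intensity / max(p2$intensity) * max(p1$intensity)
    p2$which <- reference$id
    dat <- dplyr::bind_rows(p1, p2)
  }
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = .data$mz, xend = .data$mz, y = 0, yend = .data$intensity,
      colour = .data$which
    )
  ) +
    ggplot2::geom_segment() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "m/z", y = "intensity", colour = NULL) +
    ggplot2::theme_minimal()
}
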