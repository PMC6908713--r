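#' Plot known versus predicted lifespan
#'
#' Scatter of known against predicted maximum lifespan on the natural-log
#' scale, coloured by vertebrate class, with the identity line.
#'
#' @param data Tibble with `known_years`, `predicted_years` and optionally
#'   `vertebrate_class`.
#' @return A ggplot object.
#' @export
plot_lifespan_fit <- function(data) {
  data <- as_tibble(data)
  aes_pt <- if ("vertebrate_class" %in% names(data)) {
    ggplot2::aes(log(.data$known_years), log(.data$predicted_years),
                 colour = .data$vertebrate_class)
  } else {
    ggplot2::aes(log(.data$known_years), log(.data$predicted_years))
  }
  ggplot2::ggplot(data, aes_pt) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "ln known maximum lifespan (years)",
                  y = "ln predicted maximum lifespan (years)",
                  colour = "Class") +
    ggplot2::theme_minimal()
}

#' @rdname plot_lifespan_fit
#' @param object A `clock_evaluation` from [score_predictions()].
#' @param ... Unused.
#' @export
autoplot.clock_evaluation <- function(object, ...) {
  plot_lifespan_fit(object$per_species)
}

#' Plot a TSS-flank CpG density profile
#'
#' @param profile Tibble from [tss_flank_profile()]; several species'
#'   profiles may be row-bound.
#' @return A ggplot object.
#' @export
plot_tss_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(.data$offset_start + 250, .data$density,
                               group = .data$species_id,
                               colour = .data$species_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Offset from TSS (bp, gene orientation)",
                  y = "Mean CpG density", colour = "Species") +
    ggplot2::theme_minimal()
}

#' Plot PCA scores of the density matrix
#'
#' @param pca Result of [pca_densities()].
#' @param colour_by Optional named vector (by species id) used to colour
#'   points, e.g. ln lifespan.
#' @return A ggplot object.
#' @export
plot_pca_densities <- function(pca, colour_by = NULL) {
  scores <- pca$scores
  ev <- pca$explained_variance
  if (!is.null(colour_by)) {
    scores$colour <- colour_by[scores$species_id]
    p <- ggplot2::ggplot(scores, ggplot2::aes(.data$PC1, .data$PC2,
                                              colour = .data$colour))
  } else {
    p <- ggplot2::ggplot(scores, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2])
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
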