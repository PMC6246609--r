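#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_col
#'   geom_hline labs theme_minimal facet_wrap arrow unit coord_equal
NULL

#' @export
ggplot2::autoplot

#' Biplot of a weighted CCA ordination
#'
#' Gene (or bin) points on the first two constrained axes with the
#' operational-variable arrows and their midpoints (the partition anchors).
#'
#' @param object A `wcca` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wcca <- function(object, ...) {
  if (!"axis2" %in% names(object$gene_scores)) {
    stop("need at least two constrained axes to plot")
  }
  arrows_df <- object$arrows
  ggplot(object$gene_scores, aes(x = .data$axis1, y = .data$axis2)) +
    geom_point(alpha = 0.5, size = 1) +
    geom_segment(data = arrows_df,
                 aes(x = 0, y = 0, xend = .data$axis1, yend = .data$axis2),
                 arrow = arrow(length = unit(2, "mm")), colour = "red") +
    geom_point(data = arrows_df,
               aes(x = .data$axis1 / 2, y = .data$axis2 / 2),
               shape = 4, colour = "red", size = 2) +
    ggplot2::geom_text(data = arrows_df,
                       aes(x = .data$axis1, y = .data$axis2,
                           label = .data$variable),
                       colour = "red", vjust = -0.6, size = 3) +
    coord_equal() +
    labs(x = "wCCA axis 1", y = "wCCA axis 2") +
    theme_minimal()
}

#' Plot a weighted MDS embedding
#'
#' @param object A `wmds` object.
#' @param ... Unused.
#' @return A ggplot with points sized by ordination weight.
#' @export
autoplot.wmds <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$axis1, y = .data$axis2, size = .data$weight)) +
    geom_point(alpha = 0.7) +
    ggplot2::geom_text(aes(label = .data$point), vjust = -0.8, size = 3,
                       show.legend = FALSE) +
    coord_equal() +
    labs(x = "wMDS axis 1", y = "wMDS axis 2", size = "mean mRNA-RPKM") +
    theme_minimal()
}

#' Plot community composition estimates
#'
#' @param composition Tibble `bin, frequency, method` (the pipeline's
#'   composition table).
#' @return A ggplot comparing the estimators.
#' @export
plot_composition <- function(composition) {
  ggplot(composition, aes(x = .data$bin, y = .data$frequency)) +
    geom_col() +
    facet_wrap(~method) +
    labs(x = NULL, y = "relative frequency") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot responsive-gene tallies per stimulus and taxon
#'
#' Positive counts up, negative counts down, with the multi-heme
#' cytochrome overlay.
#'
#' @param tally Output of [tally_by_taxon()].
#' @return A ggplot.
#' @export
plot_responsive_tally <- function(tally) {
  df <- tally |>
    mutate(signed_n = ifelse(.data$direction == "negative", -.data$n,
                             .data$n))
  ggplot(df, aes(x = .data$taxon, y = .data$signed_n,
                 fill = .data$direction)) +
    geom_col() +
    geom_point(data = df |> filter(.data$n_mh_cytc > 0),
               aes(y = ifelse(.data$direction == "negative",
                              -.data$n_mh_cytc, .data$n_mh_cytc)),
               colour = "gold3", size = 2, show.legend = FALSE) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    facet_wrap(~stimulus) +
    labs(x = NULL, y = "responsive genes") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  }
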