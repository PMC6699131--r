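#' Plot an IBS matrix as a heatmap
#'
#' @param object an `ibs_matrix`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ibs_matrix <- function(object, ...) {
  df <- tidy.ibs_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$ibs)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "IBS") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Stacked ancestry-coefficient barplot
#'
#' The classic population-structure plot: one bar per sample, segments by
#' ancestral group.
#'
#' @param object an `ancestry_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ancestry_fit <- function(object, ...) {
  df <- tidy.ancestry_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$coefficient,
                                   fill = .data$group)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "Ancestry coefficient", fill = "Group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Cross-entropy curve over candidate K
#'
#' @param object a `kselect_result`.
#' @param ... unused.
#' @return A ggplot with the chosen K marked.
#' @export
autoplot.kselect_result <- function(object, ...) {
  df <- object$cross_entropy_by_K
  ggplot2::ggplot(df, ggplot2::aes(.data$K, .data$cross_entropy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_K, linetype = "dashed") +
    ggplot2::labs(x = "Number of ancestral groups K",
                  y = "Masked cross-entropy") +
    ggplot2::theme_minimal()
}

#' Multidimensional scaling scatter plot
#'
#' @param object an `mds_result`.
#' @param colour_by optional named vector (by sample id) used to colour
#'   points, e.g. germplasm groups.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mds_result <- function(object, colour_by = NULL, ...) {
  df <- object$points
  if (!is.null(colour_by)) {
    df$group <- unname(colour_by[df$sample_id])
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                          colour = .data$group))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2))
  }
  ev <- object$eigenvalues
  pos <- ev[ev > 0]
  pct <- 100 * pos[1:2] / sum(pos)
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("Dimension 1 (%.1f%%)", pct[1]),
                  y = sprintf("Dimension 2 (%.1f%%)", pct[2]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Reported-versus-determined agreement tile plot
#'
#' Tabular stand-in for the Sankey view of how farmer-reported names flow
#' into DNA-determined varieties.
#'
#' @param object an `agreement_report`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.agreement_report <- function(object, ...) {
  ggplot2::ggplot(object$flow,
                  ggplot2::aes(.data$determined, .data$reported,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_viridis_c(name = "Samples") +
    ggplot2::labs(x = "Determined by DNA fingerprinting",
                  y = "Reported by farmer") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Diversity indices by germplasm group
#'
#' @param div a `diversity_report` from [group_diversity()].
#' @return A ggplot of the three indices, faceted.
#' @export
plot_diversity <- function(div) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(div),
    c("expected_heterozygosity", "shannon_index", "mean_mrd"),
    names_to = "index", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$germplasm_group, .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
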