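#' Plot the median-AASD distribution with group cutoffs
#'
#' Histogram of per-orthogroup median divergences coloured by group, with
#' the realized Group-1 and Group-2 quantile cutoffs as dashed lines.
#'
#' @param object An [assign_groups()] result.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aasd_atlas <- function(object, bins = 60, ...) {
  df <- tidy(object)
  df$group <- factor(df$group, levels = c(3, 2, 1),
                     labels = c("Group 3", "Group 2", "Group 1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_aasd,
                                   fill = .data$group)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$thresholds,
                        linetype = "dashed", colour = "grey30") +
    ggplot2::scale_fill_manual(
      values = c("Group 3" = "grey70", "Group 2" = "#fdae61",
                 "Group 1" = "#d7191c"), name = NULL) +
    ggplot2::labs(x = "median AASD (substitutions / site)",
                  y = "orthogroups") +
    ggplot2::theme_minimal()
}

#' Plot median AASD against median tip-to-tip tree distance
#'
#' Scatter of the paired per-orthogroup medians underlying a
#' [validate_aasd()] report, with the identity line and the Pearson r in
#' the subtitle.
#'
#' @param object A [validate_aasd()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aasd_validation <- function(object, ...) {
  df <- attr(object, "data")
  r <- object$r[object$term == "tip_to_tip"]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tree_median,
                                   y = .data$median_aasd)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "median tip-to-tip distance (NJ tree)",
      y = "median pairwise ML distance",
      subtitle = paste0("Pearson r = ", signif(r, 3))) +
    ggplot2::theme_minimal()
}

#' Heatmap of a per-orthogroup distance matrix
#'
#' @param object A [distance_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object; masked pairs are drawn blank.
#' @export
autoplot.aasd_dist <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species_a,
                                   y = .data$species_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = "distance") +
    ggplot2::labs(x = NULL, y = NULL, title = object$id) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
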