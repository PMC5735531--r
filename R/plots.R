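# ggplot2 visualisations for the pipeline's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a feature-usage heatmap
#'
#' Classifiers on the y axis (best objective at the top), features on
#' the x axis; cell darkness gives the fraction of selection-CV folds
#' in which the classifier's selected model used the feature.
#'
#' @param object A `screen_heatmap`.
#' @param ... Unused.
#' @method autoplot screen_heatmap
#' @export
autoplot.screen_heatmap <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$classifier,
                                   fill = .data$usage)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$classifier))) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "fold usage",
      title = sprintf("Feature usage across classifiers (%s)",
                      if (object$regularized) "L0-regularized"
                      else "non-regularized")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Plot the penalized objective along the sparsifying axis
#'
#' Mean objective with one-standard-error bars per grid point,
#' marking the unpenalized-best and the one-SE-selected points.
#'
#' @param object A `screen_selection`.
#' @param ... Unused.
#' @method autoplot screen_selection
#' @export
autoplot.screen_selection <- function(object, ...) {
  df <- tidy(object)
  axis <- object$sparsifying_param
  flag <- dplyr::case_when(df$is_theta_1se ~ "theta_1se",
                           df$is_theta_hat ~ "theta_hat",
                           TRUE ~ "grid")
  df$point <- factor(flag, levels = c("grid", "theta_hat", "theta_1se"))
  ggplot2::ggplot(df, ggplot2::aes(.data[[axis]], .data$m_sparsity)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$m_sparsity - .data$se,
                                          ymax = .data$m_sparsity + .data$se,
                                          colour = .data$point)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = axis, y = "penalized objective",
                  title = object$spec_name, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-label decision-score histograms
#'
#' Mirrors the predicted-probability histograms used to judge model
#' stability: one facet per true label.
#'
#' @param fit A `screen_fit`.
#' @param features A `screen_features` tibble.
#' @param bins Number of bins.
#' @return A ggplot object.
#' @export
plot_score_histogram <- function(fit, features, bins = 20) {
  df <- probability_histogram(fit, features, bins)
  df$label <- factor(df$label, levels = c(0, 1),
                     labels = c("non-ASD", "ASD"))
  ggplot2::ggplot(df, ggplot2::aes((.data$lower + .data$upper) / 2,
                                   .data$count)) +
    ggplot2::geom_col(width = df$upper[1] - df$lower[1]) +
    ggplot2::facet_wrap(~label, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "decision score", y = "subjects") +
    ggplot2::theme_minimal()
}
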