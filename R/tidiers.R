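# broom-style tidy()/glance() methods for the pipeline's result
# objects, so results flow straight into dplyr/ggplot2.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a phase-1 selection result
#'
#' One row per grid point, with the mean penalized objective, its
#' standard error, the mean validation AUC and mean feature count, and
#' flags marking the unpenalized-best (`theta_hat`) and one-SE-selected
#' (`theta_1se`) points.
#'
#' @param x A `screen_selection`.
#' @param ... Unused.
#' @method tidy screen_selection
#' @export
tidy.screen_selection <- function(x, ...) {
  out <- x$grid
  out$m_sparsity <- x$m_mean
  out$se <- x$se
  out$mean_auc <- x$mean_auc
  out$mean_features_used <- x$mean_used
  out$is_theta_hat <- seq_len(nrow(out)) == x$theta_hat
  out$is_theta_1se <- seq_len(nrow(out)) == x$theta_1se
  dplyr::bind_cols(tibble::tibble(classifier = x$spec_name), out)
}

#' @rdname tidy.screen_selection
#' @method glance screen_selection
#' @export
glance.screen_selection <- function(x, ...) {
  i <- x$theta_1se
  hp <- paste(names(x$grid), vapply(as.list(x$grid[i, ]), format, ""),
              sep = "=", collapse = ", ")
  tibble::tibble(
    classifier = x$spec_name, family = x$family, mu = x$mu,
    auc_kind = x$auc_kind, selected = hp,
    m_sparsity = x$m_mean[i], se = x$se[i],
    mean_auc = x$mean_auc[i], mean_features_used = x$mean_used[i]
  )
}

#' Tidy a fitted model
#'
#' One row per feature handed to the engine, flagging whether the
#' fitted model uses it; linear-form engines also report the
#' coefficient.
#'
#' @param x A `screen_fit`.
#' @param ... Unused.
#' @method tidy screen_fit
#' @export
tidy.screen_fit <- function(x, ...) {
  out <- tibble::tibble(
    feature = x$wrapper_features,
    used = x$wrapper_features %in% x$features_used
  )
  if (!is.null(x$model$beta)) {
    out$estimate <- unname(x$model$beta)
  }
  out
}

#' @rdname tidy.screen_fit
#' @method glance screen_fit
#' @export
glance.screen_fit <- function(x, ...) {
  tibble::tibble(
    classifier = x$name, family = x$family,
    n_features_used = count_features_used(x),
    threshold = x$default_threshold
  )
}

#' Tidy a feature-usage heatmap into long form
#'
#' @param x A `screen_heatmap`.
#' @param ... Unused.
#' @return Tibble with `classifier`, `feature`, `usage` in `[0, 1]`.
#' @method tidy screen_heatmap
#' @export
tidy.screen_heatmap <- function(x, ...) {
  tibble::as_tibble(x$matrix, rownames = "classifier") |>
    tidyr::pivot_longer(-"classifier", names_to = "feature",
                        values_to = "usage") |>
    dplyr::mutate(
      classifier = factor(.data$classifier, levels = rownames(x$matrix)),
      feature = factor(.data$feature, levels = colnames(x$matrix))
    )
}

#' Tidy a reduced feature set
#'
#' @param x A `screen_reduced`.
#' @param ... Unused.
#' @method tidy screen_reduced
#' @export
tidy.screen_reduced <- function(x, ...) {
  tibble::tibble(rank = seq_len(x$k), feature = x$features)
}

#' Tidy an evaluation report into a metric table
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return Tibble with `metric` and `value`, mirroring the standard
#'   accuracy panel (ROC AUC, both PR AUCs, precision,
#'   recall/sensitivity, specificity, balanced accuracy, F1).
#' @method tidy screen_report
#' @export
tidy.screen_report <- function(x, ...) {
  if (is.null(x$metrics)) {
    return(tibble::tibble(metric = character(), value = numeric()))
  }
  m <- x$metrics
  tibble::tibble(
    metric = c("auc_roc", "auc_pr_asd", "auc_pr_control", "precision",
               "recall_sensitivity", "specificity", "balanced_accuracy",
               "f1"),
    value = c(m$auc_roc, m$auc_pr_asd, m$auc_pr_control, m$precision,
              m$recall_sensitivity, m$specificity, m$balanced_accuracy,
              m$f1)
  )
}

#' @rdname tidy.screen_report
#' @method glance screen_report
#' @export
glance.screen_report <- function(x, ...) {
  if (is.null(x$metrics)) {
    return(tibble::tibble(classifier = x$spec_name, threshold = x$threshold))
  }
  dplyr::bind_cols(
    tibble::tibble(classifier = x$spec_name %||% NA_character_),
    tibble::as_tibble(x$metrics),
    tibble::as_tibble(as.list(x$confusion)),
    tibble::tibble(threshold = x$threshold)
  )
}

#' Tidy a correlation matrix into long form
#'
#' @param x A `screen_cormat`.
#' @param ... Unused.
#' @method tidy screen_cormat
#' @export
tidy.screen_cormat <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(m, rownames = "variable1") |>
    tidyr::pivot_longer(-"variable1", names_to = "variable2",
                        values_to = "correlation")
}
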