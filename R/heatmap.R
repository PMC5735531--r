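# Cross-classifier feature-usage heatmaps.

#' Build a feature-usage heatmap
#'
#' One row per classifier configuration, one column per feature; the
#' cell holds the fraction of selection-CV folds in which that
#' configuration's one-SE-selected model used the feature (1 = used in
#' every fold). Rows are sorted by descending mean objective so the
#' best-performing configurations sit at the top. With
#' `regularized = FALSE` each selection is first re-derived with the L0
#' penalty switched off ([with_penalty()] at `mu = 0`), giving the
#' companion non-regularized heatmap used for tie-breaking.
#'
#' @param results List of `screen_selection` objects sharing one
#'   feature universe and fold frame.
#' @param regularized Keep each result's own penalty (`TRUE`) or
#'   re-derive at `mu = 0` (`FALSE`).
#' @return Object of class `screen_heatmap`: the usage `matrix`
#'   (classifiers x features), the per-classifier mean `objective`, and
#'   the `regularized` flag.
#' @export
build_heatmap <- function(results, regularized = TRUE) {
  if (!length(results)) {
    abort("no selection results given", class = "screen_aggregation_error")
  }
  universe <- results[[1]]$feature_universe
  for (r in results) {
    if (!identical(r$feature_universe, universe)) {
      abort("selection results disagree on the feature universe",
            class = "screen_aggregation_error")
    }
  }
  if (!regularized) {
    results <- lapply(results, with_penalty, mu = 0)
  }
  rows <- vapply(results, function(r) {
    sets <- r$fold_features[[r$theta_1se]]
    vapply(universe,
           function(f) mean(vapply(sets, function(s) f %in% s, TRUE)),
           0)
  }, numeric(length(universe)))
  mat <- t(rows)
  rownames(mat) <- vapply(results, function(r) r$spec_name, "")
  objective <- vapply(results, function(r) r$m_mean[r$theta_1se], 0)
  ord <- order(-objective, seq_along(objective))
  structure(
    list(matrix = mat[ord, , drop = FALSE],
         objective = setNames(objective[ord], rownames(mat)[ord]),
         regularized = regularized),
    class = "screen_heatmap"
  )
}

#' Aggregate feature usage across classifiers
#'
#' Mean of the classifier-level fold fractions per feature — the
#' consensus vote the reduced sets are ranked by.
#'
#' @param heatmap A `screen_heatmap`.
#' @param exclude_degenerate Drop classifiers whose mean AUC at the
#'   selected grid point is at or below `0.55` before averaging
#'   (off by default).
#' @param results The originating list of `screen_selection` objects;
#'   only needed when `exclude_degenerate = TRUE`.
#' @return Named numeric vector of aggregate usage in `[0, 1]`.
#' @export
aggregate_usage <- function(heatmap, exclude_degenerate = FALSE,
                            results = NULL) {
  mat <- heatmap$matrix
  if (exclude_degenerate) {
    if (is.null(results)) {
      abort("need `results` to identify degenerate classifiers",
            class = "screen_input_error")
    }
    auc <- vapply(results, function(r) r$mean_auc[r$theta_1se], 0)
    names(auc) <- vapply(results, function(r) r$spec_name, "")
    keep <- rownames(mat)[auc[rownames(mat)] > 0.55]
    mat <- mat[keep, , drop = FALSE]
  }
  colMeans(mat)
}

#' Derive the consensus reduced-k feature set
#'
#' Features are ranked by their aggregate usage in the L0-regularized
#' (`primary`) heatmap. Ties at the k-boundary are broken by the
#' aggregate usage in the non-regularized (`secondary`) heatmap;
#' residual ties fall back to feature-name order. Every invocation of
#' the secondary heatmap is recorded in `tie_log`.
#'
#' @param primary `screen_heatmap` built with the L0 penalty.
#' @param secondary `screen_heatmap` built without it.
#' @param k Target set size.
#' @param ... Passed to [aggregate_usage()] (e.g.
#'   `exclude_degenerate`).
#' @return Object of class `screen_reduced`: `k`, the ordered
#'   `features`, and a `tie_log` tibble.
#' @export
derive_reduced_set <- function(primary, secondary, k, ...) {
  feats <- colnames(primary$matrix)
  if (!identical(feats, colnames(secondary$matrix))) {
    abort("heatmaps disagree on the feature universe",
          class = "screen_aggregation_error")
  }
  if (k < 1 || k > length(feats)) {
    abort(sprintf("k must be in 1..%d", length(feats)),
          class = "screen_parameter_error")
  }
  p_use <- aggregate_usage(primary, ...)
  s_use <- aggregate_usage(secondary, ...)
  ord <- order(-p_use, -s_use, feats)
  ranked <- feats[ord]
  chosen <- ranked[seq_len(k)]

  tie_log <- tibble::tibble(tied = list(), winner = list(),
                            source = character())
  if (k < length(feats)) {
    boundary_val <- p_use[ranked[k]]
    group <- feats[p_use == boundary_val]
    if (length(setdiff(group, chosen)) > 0 &&
        length(intersect(group, chosen)) > 0) {
      winners <- intersect(ranked, intersect(group, chosen))
      source <- if (length(unique(s_use[group])) > 1) "secondary" else "name"
      tie_log <- tibble::tibble(tied = list(sort(group)),
                                winner = list(winners), source = source)
    }
  }
  structure(list(k = as.integer(k), features = chosen, tie_log = tie_log),
            class = "screen_reduced")
}

#' Write a heatmap as CSV (plus JSON sidecar)
#'
#' The CSV holds the classifier x feature usage matrix with classifier
#' names in the first column; the sidecar records row order and the
#' regularized flag.
#'
#' @param heatmap A `screen_heatmap`.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @export
write_heatmap_csv <- function(heatmap, path) {
  df <- tibble::as_tibble(heatmap$matrix, rownames = "classifier")
  readr::write_csv(df, path)
  jsonlite::write_json(
    list(classifier_order = rownames(heatmap$matrix),
         regularized = heatmap$regularized),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(heatmap)
}

#' @export
print.screen_heatmap <- function(x, ...) {
  cat(sprintf("<screen_heatmap> %d classifiers x %d features (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$regularized) "L0-regularized" else "non-regularized"))
  top <- sort(colMeans(x$matrix), decreasing = TRUE)
  cat("  top features:",
      paste(sprintf("%s (%.2f)", names(head(top, 5)), head(top, 5)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.screen_reduced <- function(x, ...) {
  cat(sprintf("<screen_reduced> k = %d: %s\n", x$k,
              paste(x$features, collapse = ", ")))
  if (nrow(x$tie_log)) {
    cat(sprintf("  %d boundary tie(s) broken by %s\n", nrow(x$tie_log),
                paste(unique(x$tie_log$source), collapse = "/")))
  }
  invisible(x)
}
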