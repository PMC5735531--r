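# Phase 1: stratified 10-fold cross-validation with a nested grid
# search, the L0-penalized objective, and the one-standard-error rule.

#' Stratified cross-validation folds
#'
#' Assigns each subject a fold in `1..n_folds`, balanced within each
#' class. The assignment depends only on the labels and the seed, so
#' every classifier configuration run with the same seed shares the
#' same resampling frame — a prerequisite for comparing feature usage
#' across classifiers on the heatmap.
#'
#' @param y Binary labels.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer fold vector of length `length(y)`.
#' @export
make_folds <- function(y, n_folds = 10, seed = 1L) {
  folds <- integer(length(y))
  for (cl in sort(unique(y))) {
    members <- which(y == cl)
    if (length(members) < n_folds) {
      abort(sprintf(
        "class %s has %d members, fewer than n_folds = %d; cannot stratify",
        cl, length(members), n_folds), class = "screen_cv_error")
    }
    set.seed(child_seed(seed, 37 + cl))
    folds[sample(members)] <- rep_len(seq_len(n_folds), length(members))
  }
  folds
}

hyper_grid_table <- function(spec, total_features) {
  grid <- expand.grid(spec$hyper_grid, KEEP.OUT.ATTRS = FALSE)
  if (spec$wrapper %in% c("ANOVA", "Tree") && "k" %in% names(grid)) {
    grid <- grid[grid$k <= total_features, , drop = FALSE]
    rownames(grid) <- NULL
  }
  tibble::as_tibble(grid)
}

#' Run the phase-1 selection cross-validation for one configuration
#'
#' For every point of the configuration's hyperparameter grid this runs
#' a stratified `n_folds`-fold cross-validation on the training
#' partition: each fold's model is fit on the remaining folds (wrapper
#' first, imbalance handled per the configuration, undersampling drawn
#' inside the training folds only), scored on the held-out fold, and
#' its validation AUC and number of features used are recorded. The
#' penalized objective `m_sparsity = AUC - mu * used / total` is
#' averaged over folds; `theta_hat` maximizes the mean objective and
#' `theta_1se` is the most parsimonious grid point within one standard
#' error of it (see [one_se_select()]).
#'
#' @param features Training-partition `screen_features`.
#' @param spec One registry row.
#' @param mu L0 penalty coefficient (default 0.1).
#' @param auc_kind AUC variant driving the objective: `"ROC"`
#'   (default), `"PR-ASD"` or `"PR-control"`.
#' @param n_folds Folds (default 10).
#' @param seed Integer seed fixing folds and undersampling draws.
#' @return An object of class `screen_selection` with the grid, per-fold
#'   AUCs, feature counts and feature sets, the penalized objective and
#'   its standard error, and the indices `theta_hat` / `theta_1se`.
#' @export
run_selection_cv <- function(features, spec, mu = 0.1,
                             auc_kind = c("ROC", "PR-ASD", "PR-control"),
                             n_folds = 10, seed = 1L) {
  auc_kind <- match.arg(auc_kind)
  spec <- as_spec(spec)
  y <- features$binary_label
  total_features <- length(feature_names(features))
  grid <- hyper_grid_table(spec, total_features)
  folds <- make_folds(y, n_folds, seed)

  n_grid <- nrow(grid)
  fold_auc <- matrix(NA_real_, n_grid, n_folds)
  fold_used <- matrix(NA_real_, n_grid, n_folds)
  fold_features <- lapply(seq_len(n_grid), function(i) vector("list", n_folds))

  for (f in seq_len(n_folds)) {
    tr <- features[folds != f, , drop = FALSE]
    tr <- new_screen_features(tr, attr(features, "n_items"),
                              attr(features, "age_months")[folds != f])
    va_x <- feature_matrix(features)[folds == f, , drop = FALSE]
    va_y <- y[folds == f]
    fseed <- child_seed(seed, 1000 + f)
    for (i in seq_len(n_grid)) {
      hp <- as.list(grid[i, , drop = FALSE])
      fit <- fit_model(spec, hp, tr, seed = fseed)
      scores <- if (fit$engine == "constant") {
        rep(0, nrow(va_x))
      } else {
        engine_score(fit, va_x[, fit$wrapper_features, drop = FALSE])
      }
      fold_auc[i, f] <- switch(auc_kind,
        ROC = auc_roc(scores, va_y),
        `PR-ASD` = auc_pr(scores, va_y, positive = "ASD"),
        `PR-control` = auc_pr(scores, va_y, positive = "control")
      )
      fold_used[i, f] <- count_features_used(fit)
      fold_features[[i]][[f]] <- fit$features_used
    }
  }

  result <- structure(
    list(spec_name = spec$name, family = spec$family,
         sparsifying_param = spec$sparsifying_param,
         parsimony = spec$parsimony, grid = grid,
         fold_auc = fold_auc, fold_used = fold_used,
         fold_features = fold_features,
         total_features = total_features,
         feature_universe = feature_names(features),
         auc_kind = auc_kind, n_folds = n_folds, seed = seed),
    class = "screen_selection"
  )
  with_penalty(result, mu)
}

#' Re-derive the selection under a different penalty coefficient
#'
#' The per-fold AUCs, feature counts and feature sets do not depend on
#' `mu`; only the objective and the selected grid points do. This
#' recomputes `m_sparsity`, its standard error, `theta_hat` and
#' `theta_1se` from the stored fold-level results — e.g. `mu = 0`
#' yields the non-regularized selection used for the secondary heatmap.
#'
#' @param result A `screen_selection`.
#' @param mu New penalty coefficient.
#' @return The updated `screen_selection`.
#' @export
with_penalty <- function(result, mu) {
  m_fold <- m_sparsity(result$fold_auc, result$fold_used, mu,
                       result$total_features)
  result$mu <- mu
  result$m_mean <- rowMeans(m_fold)
  result$se <- apply(m_fold, 1, sd) / sqrt(result$n_folds)
  result$mean_auc <- rowMeans(result$fold_auc)
  result$mean_used <- rowMeans(result$fold_used)
  result$theta_hat <- which.max(result$m_mean)
  result$theta_1se <- one_se_select(result$grid, result$m_mean, result$se,
                                    result$parsimony,
                                    first_axis = result$sparsifying_param)
  result
}

#' One-standard-error selection rule
#'
#' Among grid points whose mean objective is within one standard error
#' of the best point's, returns the most parsimonious one. Parsimony is
#' compared lexicographically over the grid axes — the sparsifying axis
#' first, then the remaining axes in declared order — with each axis
#' oriented by its `parsimony` direction (`"high"` = larger values are
#' more parsimonious, e.g. penalties; `"low"` = smaller values are,
#' e.g. k, tree depth, tree count). Remaining ties resolve to the
#' earliest grid row, so the choice is deterministic.
#'
#' @param grid Data frame of grid-axis values, one row per grid point.
#' @param objective Mean (penalized) objective per grid point.
#' @param se Standard error per grid point (only the best point's is
#'   used for the threshold); scalar or vector.
#' @param parsimony Named character vector of directions per axis.
#' @param first_axis Axis compared first (default: first name of
#'   `parsimony`).
#' @return Integer index of the selected grid row.
#' @export
one_se_select <- function(grid, objective, se, parsimony,
                          first_axis = NULL) {
  if (!nrow(grid)) abort("empty grid", class = "screen_input_error")
  se <- rep_len(se, length(objective))
  best <- which.max(objective)
  eligible <- which(objective >= objective[best] - se[best] - 1e-12)
  axes <- names(parsimony)
  first_axis <- first_axis %||% axes[1]
  axes <- c(first_axis, setdiff(axes, first_axis))
  keys <- lapply(axes, function(a) {
    v <- grid[[a]][eligible]
    if (parsimony[[a]] == "high") -v else v
  })
  keys <- c(keys, list(eligible))  # final tie-break: declaration order
  eligible[do.call(order, keys)[1]]
}

#' Run phase-1 selection for several configurations
#'
#' Convenience wrapper running [run_selection_cv()] for each registry
#' row with a shared seed, hence a shared fold frame.
#'
#' @param features Training-partition `screen_features`.
#' @param registry A `screen_registry` (or subset of its rows).
#' @inheritParams run_selection_cv
#' @return Named list of `screen_selection` objects.
#' @export
run_selection_many <- function(features, registry, mu = 0.1,
                               auc_kind = "ROC", n_folds = 10, seed = 1L) {
  out <- lapply(seq_len(nrow(registry)), function(i) {
    run_selection_cv(features, registry[i, , drop = FALSE], mu = mu,
                     auc_kind = auc_kind, n_folds = n_folds, seed = seed)
  })
  names(out) <- registry$name
  out
}

#' @export
print.screen_selection <- function(x, ...) {
  cat(sprintf(
    "<screen_selection> %s: %d grid points x %d folds (mu = %g, %s)\n",
    x$spec_name, nrow(x$grid), x$n_folds, x$mu, x$auc_kind))
  show <- function(i, tag) {
    hp <- paste(names(x$grid), vapply(as.list(x$grid[i, ]), format, ""),
                sep = " = ", collapse = ", ")
    cat(sprintf("  %s: %s | objective %.4f (SE %.4f), AUC %.4f, %.1f features\n",
                tag, hp, x$m_mean[i], x$se[i], x$mean_auc[i], x$mean_used[i]))
  }
  show(x$theta_hat, "theta_hat")
  show(x$theta_1se, "theta_1se")
  invisible(x)
}
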