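# Phase 2: AUC-only retuning on the reduced feature set.
# Phase 3: held-out evaluation with the full metric panel.

#' Phase-2 hyperparameter tuning on a reduced feature set
#'
#' Stratified cross-validated grid search maximizing mean fold AUC_ROC
#' only — no sparsity penalty and no feature-selection wrapper (the
#' feature set is already fixed). Ties on the objective resolve to the
#' more parsimonious grid point, so the choice is deterministic.
#'
#' @param features Training `screen_features` already restricted to the
#'   reduced set (see [select_features()]).
#' @param spec One registry row.
#' @param n_folds Folds (default 10).
#' @param seed Integer seed.
#' @return List of class `screen_tuning`: `hyperparams`, `mean_auc`,
#'   `se`, `spec_name` and the full `grid` with per-point mean AUCs.
#' @export
tune_on_reduced <- function(features, spec, n_folds = 10, seed = 1L) {
  if (!length(feature_names(features))) {
    abort("reduced feature set is empty", class = "screen_input_error")
  }
  spec <- as_spec(spec)
  spec <- drop_wrapper(spec)
  sel <- run_selection_cv(features, spec_as_row(spec), mu = 0,
                          auc_kind = "ROC", n_folds = n_folds, seed = seed)
  # argmax of mean AUC; exact ties resolved by parsimony
  best <- one_se_select(sel$grid, sel$m_mean, 0, sel$parsimony,
                        first_axis = sel$sparsifying_param)
  structure(
    list(spec_name = spec$name,
         hyperparams = as.list(sel$grid[best, , drop = FALSE]),
         mean_auc = sel$m_mean[best], se = sel$se[best],
         grid = sel$grid, grid_mean_auc = sel$m_mean,
         n_folds = n_folds, seed = seed),
    class = "screen_tuning"
  )
}

# Phase 2 drops the feature-selection wrapper and its k axis.
drop_wrapper <- function(spec) {
  if (spec$wrapper != "NS") {
    spec$hyper_grid[[spec$sparsifying_param]] <- NULL
    spec$parsimony <- spec$parsimony[names(spec$parsimony) !=
                                       spec$sparsifying_param]
    if (!length(spec$hyper_grid)) {
      spec$hyper_grid <- list(.const = 0)
      spec$parsimony <- c(.const = "high")
    }
    spec$sparsifying_param <- names(spec$parsimony)[1]
    spec$wrapper <- "NS"
  }
  spec
}

spec_as_row <- function(spec) {
  tibble::tibble(
    name = spec$name, family = spec$family, engine = spec$engine,
    wrapper = spec$wrapper, imbalance_mode = spec$imbalance_mode,
    uses_ordinal_target = spec$uses_ordinal_target,
    sparsifying_param = spec$sparsifying_param,
    hyper_grid = list(spec$hyper_grid), parsimony = list(spec$parsimony),
    engine_args = list(spec$engine_args)
  )
}

#' Phase-3 held-out evaluation
#'
#' Scores the fitted model on the test partition and reports the full
#' metric panel: AUC_ROC, AUC_PR with ASD and with controls as the
#' positive class (threshold-free), plus the confusion-matrix metrics
#' at the given decision threshold — precision, recall/sensitivity,
#' specificity, balanced accuracy and F1, all with ASD as the positive
#' class. Zero-denominator metrics are reported as `NA` with a warning,
#' never silently 0.
#'
#' @param fit A `screen_fit`.
#' @param features Test-partition `screen_features`.
#' @param threshold Decision cutoff on the score; default is the fit's
#'   natural threshold (0.5 for probability scorers, 0 for margins).
#' @return Object of class `screen_report`: the metrics, confusion
#'   counts, threshold, and a per-subject `scores` tibble.
#' @export
evaluate_on_test <- function(fit, features, threshold = NULL) {
  scores <- predict(fit, features)
  y <- features$binary_label
  threshold <- threshold %||% fit$default_threshold
  scores_tbl <- tibble::tibble(
    subject_id = features$subject_id, label = y, score = scores,
    predicted = as.integer(scores >= threshold)
  )
  if (length(unique(y)) < 2) {
    warn("test set contains a single class; only scores are reported")
    return(structure(list(metrics = NULL, confusion = NULL,
                          threshold = threshold, scores = scores_tbl,
                          spec_name = fit$name),
                     class = "screen_report"))
  }
  pred <- scores_tbl$predicted
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  metrics <- confusion_metrics(tp, fp, tn, fn)
  metrics$auc_roc <- auc_roc(scores, y)
  metrics$auc_pr_asd <- auc_pr(scores, y, positive = "ASD")
  metrics$auc_pr_control <- auc_pr(scores, y, positive = "control")
  structure(
    list(metrics = metrics,
         confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
         threshold = threshold, scores = scores_tbl,
         spec_name = fit$name),
    class = "screen_report"
  )
}

# Confusion-derived metrics; NA (with a warning) on zero denominators.
confusion_metrics <- function(tp, fp, tn, fn) {
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined (zero denominator); reported as NA", what))
      return(NA_real_)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall/sensitivity")
  specificity <- safe_div(tn, tn + fp, "specificity")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    warn("F1 undefined; reported as NA")
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall_sensitivity = recall,
       specificity = specificity,
       balanced_accuracy = (recall + specificity) / 2, f1 = f1)
}

#' Pairwise Pearson correlation matrix
#'
#' Correlations between selected features and covariates (age, gender,
#' class indicator). Constant columns yield undefined (NA)
#' correlations, reported with a warning rather than silently zeroed.
#'
#' @param data Data frame / tibble of numeric columns.
#' @return A symmetric correlation matrix of class `screen_cormat` with
#'   unit diagonal.
#' @export
correlation_matrix <- function(data) {
  data <- as.data.frame(data)
  if (nrow(data) < 3) {
    abort("need at least 3 subjects for correlations",
          class = "screen_input_error")
  }
  constant <- vapply(data, function(col) sd(col) == 0, TRUE)
  if (any(constant)) {
    warn(sprintf("constant column(s) %s: correlations undefined (NA)",
                 paste(names(data)[constant], collapse = ", ")))
  }
  m <- suppressWarnings(stats::cor(as.matrix(data)))
  d <- diag(m)
  d[!constant] <- 1
  diag(m) <- d
  structure(m, class = c("screen_cormat", class(m)))
}

#' Binned decision-score histogram per label
#'
#' Mirrors the predicted-probability histograms used to inspect model
#' stability: per-label counts of subjects falling in each score bin.
#'
#' @param fit A `screen_fit`.
#' @param features A `screen_features` tibble.
#' @param bins Number of bins (>= 2).
#' @return Tibble with `label`, `bin`, `lower`, `upper`, `count`;
#'   per-label counts sum to the label's subject count.
#' @export
probability_histogram <- function(fit, features, bins = 10) {
  if (bins < 2) {
    abort("bins must be >= 2", class = "screen_parameter_error")
  }
  scores <- predict(fit, features)
  y <- features$binary_label
  rng <- range(scores)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  out <- lapply(sort(unique(y)), function(cl) {
    cnt <- graphics::hist(scores[y == cl], breaks = breaks, plot = FALSE,
                          include.lowest = TRUE, right = FALSE)$counts
    tibble::tibble(label = cl, bin = seq_len(bins),
                   lower = breaks[-length(breaks)], upper = breaks[-1],
                   count = cnt)
  })
  dplyr::bind_rows(out)
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %s (threshold %.3g)\n",
              x$spec_name %||% "?", x$threshold))
  if (is.null(x$metrics)) {
    cat("  single-class test set: scores only\n")
    return(invisible(x))
  }
  m <- x$metrics
  rows <- c("Area under ROC" = m$auc_roc,
            "AUC PR (ASD positive)" = m$auc_pr_asd,
            "AUC PR (control positive)" = m$auc_pr_control,
            "Precision" = m$precision,
            "Recall/sensitivity" = m$recall_sensitivity,
            "Specificity" = m$specificity,
            "Balanced accuracy" = m$balanced_accuracy,
            "F1 score" = m$f1)
  for (nm in names(rows)) cat(sprintf("  %-26s %.3f\n", nm, rows[[nm]]))
  invisible(x)
}
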