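# Ranking metrics and the L0-penalized grid-search objective.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability: the proportion
#' of (positive, negative) score pairs where the positive scores higher,
#' counting ties as one half.
#'
#' @param scores Real-valued decision scores, higher = more ASD-like.
#' @param labels Binary labels in `{0, 1}`.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  check_metric_inputs(scores, labels)
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-curve area over the sweep of all decision thresholds: with
#' thresholds descending, the area is the sum of precision times the
#' increment in recall at each distinct score. With
#' `positive = "control"` the score polarity is flipped (scores are
#' negated and labels complemented) so that controls — the minority
#' class the instrument struggles with — act as the positive class.
#'
#' @inheritParams auc_roc
#' @param positive Which class counts as positive: `"ASD"` (label 1) or
#'   `"control"` (label 0).
#' @return Area under the precision-recall step curve in `[0, 1]`.
#' @export
auc_pr <- function(scores, labels, positive = c("ASD", "control")) {
  positive <- match.arg(positive)
  check_metric_inputs(scores, labels)
  if (positive == "control") {
    scores <- -scores
    labels <- 1 - labels
  }
  if (sum(labels == 1) == 0) {
    abort("no positive-class subjects; precision-recall undefined",
          class = "screen_metric_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores: cumulative counts at each distinct threshold
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1 - y)[last_of_group]
  recall <- tp / sum(y)
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

check_metric_inputs <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("scores and labels must have equal length",
          class = "screen_metric_error")
  }
  if (any(!is.finite(scores))) {
    abort("scores must be finite", class = "screen_metric_error")
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    abort("labels must contain both classes coded 0/1",
          class = "screen_metric_error")
  }
  invisible(TRUE)
}

#' L0-penalized grid-search objective
#'
#' `m_sparsity = auc - mu * n_used / total_features`: the model's AUC
#' minus a penalty proportional to the fraction of available features it
#' uses. With `mu = 0` or a zero-feature model the objective equals the
#' AUC; a full-feature model is penalized by exactly `mu`.
#'
#' @param auc AUC value(s) in `[0, 1]`.
#' @param n_used Number of features the candidate model uses.
#' @param mu Penalty coefficient (default 0.1).
#' @param total_features Total number of available features.
#' @return Penalized objective value(s).
#' @export
m_sparsity <- function(auc, n_used, mu = 0.1, total_features) {
  if (any(auc < 0 | auc > 1)) {
    abort("auc must be in [0, 1]", class = "screen_domain_error")
  }
  if (mu < 0) abort("mu must be >= 0", class = "screen_domain_error")
  if (total_features < 1) {
    abort("total_features must be >= 1", class = "screen_domain_error")
  }
  if (any(n_used < 0 | n_used > total_features)) {
    abort("n_used must be between 0 and total_features",
          class = "screen_domain_error")
  }
  auc - mu * n_used / total_features
}
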