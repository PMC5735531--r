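# Fixtures are built in code at test time.

# Small cohort with planted signal in items 1..3.
small_cohort <- function(n = 200, seed = 42, effect = 1.2, miss = 0.05,
                         props = c(0.10, 0.30, 0.60), n_items = 10) {
  simulate_cohort(cohort_config(
    n_subjects = n, n_items = n_items, class_proportions = props,
    informative_items = 1:3, effect_size = effect,
    missing_rates = miss, seed = seed
  ))
}

# Hand-built 3-subject score sheet for direct-construction oracles.
hand_sheets <- function() {
  tibble::tibble(
    subject_id = c("A", "B", "C"),
    item_01 = c(0L, 1L, 3L),
    item_02 = c(2L, 8L, 0L),
    item_03 = c(9L, 1L, NA),
    age_months = c(48, 72, 96),
    gender = c("male", "female", "male"),
    diagnosis = c("non-ASD", "spectrum", "autism")
  )
}

# Linearly separable two-feature cohort encoded as screen_features.
separable_features <- function(n = 60, seed = 5) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  tbl <- tibble::tibble(
    subject_id = sprintf("P%03d", seq_len(n)),
    ordinal_label = ifelse(y == 1, 2L, 0L),
    binary_label = y,
    f1 = y * 2 + runif(n) * 0.5,
    f2 = runif(n) * 3
  )
  sparsescreen:::new_screen_features(tbl, n_items = 1,
                                     age_months = rep(60, n))
}

# Encoded mid-size cohort shared by fit/selection tests.
encoded_cohort <- function(n = 300, seed = 9, effect = 1.2, n_items = 10) {
  encode_features(small_cohort(n = n, seed = seed, effect = effect,
                               n_items = n_items))
}

# Brute-force PR-curve oracle: precision/recall threshold sweep.
auc_pr_oracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  recall <- prec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    recall[i] <- sum(pred & labels == 1) / sum(labels == 1)
    prec[i] <- sum(pred & labels == 1) / sum(pred)
  }
  sum(diff(c(0, recall)) * prec)
}

# Brute-force one-SE oracle: filter by the constraint, then scan for
# the lexicographic parsimony maximum.
one_se_oracle <- function(grid, objective, se, parsimony, first_axis) {
  best <- which.max(objective)
  ok <- which(objective >= objective[best] - se[best] - 1e-12)
  axes <- c(first_axis, setdiff(names(parsimony), first_axis))
  better <- function(i, j) {
    for (a in axes) {
      vi <- grid[[a]][i]; vj <- grid[[a]][j]
      if (vi == vj) next
      more_parsimonious <- if (parsimony[[a]] == "high") vi > vj else vi < vj
      return(more_parsimonious)
    }
    i < j
  }
  winner <- ok[1]
  for (i in ok[-1]) if (better(i, winner)) winner <- i
  winner
}

# Construct a synthetic screen_selection from given fold matrices, for
# oracle tests that need full control of the grid.
synthetic_selection <- function(grid, fold_auc, fold_used, parsimony,
                                sparsifier = names(parsimony)[1],
                                total_features = 58, mu = 0.1,
                                features = NULL) {
  n_grid <- nrow(grid)
  n_folds <- ncol(fold_auc)
  fold_features <- lapply(seq_len(n_grid), function(i) {
    lapply(seq_len(n_folds), function(f) {
      if (is.null(features)) character() else features[[i]][[f]]
    })
  })
  res <- structure(
    list(spec_name = "synthetic", family = "synthetic",
         sparsifying_param = sparsifier, parsimony = parsimony,
         grid = tibble::as_tibble(grid),
         fold_auc = fold_auc, fold_used = fold_used,
         fold_features = fold_features, total_features = total_features,
         feature_universe = paste0("f", seq_len(total_features)),
         auc_kind = "ROC", n_folds = n_folds, seed = 1L),
    class = "screen_selection"
  )
  with_penalty(res, mu)
}
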