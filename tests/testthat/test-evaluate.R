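# Phase-2 tuning, phase-3 evaluation metrics, correlations, and score
# histograms.

# Craft scores/labels realizing a given confusion table at cutoff 0.5.
confusion_scores <- function(tp, fn, tn, fp) {
  list(
    scores = c(seq(0.6, 0.9, length.out = tp),
               seq(0.1, 0.4, length.out = fn),
               seq(0.1, 0.4, length.out = tn),
               seq(0.6, 0.9, length.out = fp)),
    labels = c(rep(1, tp + fn), rep(0, tn + fp))
  )
}

manual_fit <- function(beta, features, intercept = 0, threshold = 0.5) {
  structure(
    list(name = "manual", engine = "ols_ordinal", family = "manual",
         hyperparams = list(), wrapper_features = names(beta),
         features_used = names(beta)[beta != 0],
         model = list(beta = beta, intercept = intercept),
         default_threshold = threshold, flip = 1),
    class = "screen_fit"
  )
}

test_that("confusion metrics follow their identities", {
  cs <- confusion_scores(tp = 95, fn = 5, tn = 9, fp = 1)
  fit <- manual_fit(c(s = 1), NULL)
  fe_tbl <- tibble::tibble(subject_id = as.character(seq_along(cs$labels)),
                           ordinal_label = cs$labels, binary_label = cs$labels,
                           s = cs$scores)
  fe <- sparsescreen:::new_screen_features(fe_tbl, 1, rep(60, nrow(fe_tbl)))
  rep <- evaluate_on_test(fit, fe)
  expect_equal(rep$confusion, c(TP = 95, FP = 1, TN = 9, FN = 5))
  expect_equal(rep$metrics$recall_sensitivity, 0.95)
  expect_equal(rep$metrics$specificity, 0.90)
  expect_equal(rep$metrics$balanced_accuracy, 0.925)
  expect_equal(rep$metrics$precision, 95 / 96)
})

test_that("sensitivity 0.90 with specificity 0.89 rounds to 0.90 balanced", {
  cs <- confusion_scores(tp = 90, fn = 10, tn = 89, fp = 11)
  fit <- manual_fit(c(s = 1), NULL)
  fe_tbl <- tibble::tibble(subject_id = as.character(seq_along(cs$labels)),
                           ordinal_label = cs$labels, binary_label = cs$labels,
                           s = cs$scores)
  fe <- sparsescreen:::new_screen_features(fe_tbl, 1, rep(60, nrow(fe_tbl)))
  m <- evaluate_on_test(fit, fe)$metrics
  expect_equal(m$recall_sensitivity, 0.90)
  expect_equal(m$specificity, 0.89)
  expect_equal(m$balanced_accuracy, 0.895)
  expect_equal(round(m$balanced_accuracy, 1), 0.9)
})

test_that("a perfect scorer earns a perfect panel", {
  fe <- separable_features()
  spec <- registry_spec(build_registry(), "logistic_l2")
  fit <- fit_model(spec, list(lambda = 0.001), fe, seed = 1)
  m <- evaluate_on_test(fit, fe)$metrics
  for (v in unlist(m)) expect_equal(v, 1.0)
})

test_that("metric identities hold on randomized confusion tables", {
  set.seed(66)
  for (i in 1:30) {
    counts <- sample(1:40, 4, replace = TRUE)
    m <- sparsescreen:::confusion_metrics(counts[1], counts[2],
                                          counts[3], counts[4])
    tp <- counts[1]; fp <- counts[2]; tn <- counts[3]; fn <- counts[4]
    expect_equal(m$precision, tp / (tp + fp))
    expect_equal(m$recall_sensitivity, tp / (tp + fn))
    expect_equal(m$specificity, tn / (tn + fp))
    expect_equal(m$balanced_accuracy,
                 (m$recall_sensitivity + m$specificity) / 2)
    expect_equal(m$f1, 2 * m$precision * m$recall_sensitivity /
                   (m$precision + m$recall_sensitivity))
    for (v in unlist(m)) {
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
  }
  w <- capture_warnings(m0 <- sparsescreen:::confusion_metrics(0, 0, 5, 5))
  expect_true(any(grepl("precision", w)))
  expect_true(any(grepl("F1", w)))
  expect_true(is.na(m0$precision))
  expect_true(is.na(m0$f1))
})

test_that("report AUC agrees with the metric module on the same scores", {
  fe <- encoded_cohort(n = 150, seed = 31)
  spec <- registry_spec(build_registry(), "logistic_l2")
  fit <- fit_model(spec, list(lambda = 0.1), fe, seed = 1)
  rep <- evaluate_on_test(fit, fe)
  expect_equal(rep$metrics$auc_roc,
               auc_roc(rep$scores$score, rep$scores$label))
  expect_equal(rep$metrics$auc_pr_control,
               auc_pr(rep$scores$score, rep$scores$label,
                      positive = "control"))
})

test_that("single-class test sets degrade to a score export with warning", {
  fe <- separable_features()
  keep <- fe$binary_label == 1
  fe1 <- sparsescreen:::new_screen_features(fe[keep, ], 1, rep(60, sum(keep)))
  fit <- manual_fit(c(f1 = 1, f2 = 0), NULL)
  expect_warning(rep <- evaluate_on_test(fit, fe1), "single class")
  expect_null(rep$metrics)
  expect_equal(nrow(rep$scores), sum(keep))
})

test_that("phase-2 tuning maximizes plain AUC deterministically", {
  fe <- separable_features(n = 100, seed = 8)
  spec <- registry_spec(build_registry(), "logistic_l2")
  # singleton grid returns its only point
  spec1 <- spec
  spec1$hyper_grid <- list(list(lambda = 0.5))
  t1 <- tune_on_reduced(fe, spec1, n_folds = 5, seed = 2)
  expect_equal(t1$hyperparams$lambda, 0.5)
  expect_equal(t1$mean_auc, 1.0)  # separable fixture

  t2 <- tune_on_reduced(fe, spec, n_folds = 5, seed = 2)
  t3 <- tune_on_reduced(fe, spec, n_folds = 5, seed = 2)
  expect_identical(t2, t3)
  expect_error(tune_on_reduced(select_features(fe, character()), spec),
               class = "screen_input_error")
})

test_that("phase-2 tuning drops the feature-selection wrapper", {
  fe <- encoded_cohort(n = 120, seed = 32)
  red <- feature_names(fe)[1:5]
  spec <- registry_spec(build_registry(), "svm_radial")
  tn <- tune_on_reduced(select_features(fe, red), spec, n_folds = 5, seed = 1)
  expect_false("k" %in% names(tn$hyperparams))
  fit <- fit_model(sparsescreen:::spec_as_row(
    sparsescreen:::drop_wrapper(sparsescreen:::as_spec(spec))),
    tn$hyperparams, select_features(fe, red), seed = 1)
  expect_setequal(fit$wrapper_features, red)
})

test_that("correlation matrices match the hand Pearson formula", {
  set.seed(77)
  d <- as.data.frame(matrix(rnorm(60), 10, 6))
  cm <- correlation_matrix(d)
  hand <- function(a, b) {
    mean((a - mean(a)) * (b - mean(b))) /
      (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  }
  for (i in 1:6) for (j in 1:6) {
    expect_lt(abs(cm[i, j] - hand(d[[i]], d[[j]])), 1e-12)
  }
  expect_equal(unname(diag(cm)), rep(1, 6))
  expect_lt(max(abs(cm - t(cm))), 1e-12)

  # duplicated column and orthogonal contrasts
  d2 <- data.frame(a = c(1, 1, -1, -1), b = c(1, 1, -1, -1),
                   c = c(1, -1, 1, -1))
  cm2 <- correlation_matrix(d2)
  expect_equal(cm2["a", "b"], 1.0)
  expect_lt(abs(cm2["a", "c"]), 1e-12)

  # constant columns: undefined, not zero
  expect_warning(cm3 <- correlation_matrix(data.frame(a = 1:5, b = rep(2, 5))),
                 "constant")
  expect_true(is.na(cm3["a", "b"]))
  expect_error(correlation_matrix(data.frame(a = 1:2)),
               class = "screen_input_error")
})

test_that("score histograms conserve per-label counts", {
  fe <- separable_features(n = 80)
  fit <- manual_fit(c(f1 = 1, f2 = 0), NULL)
  h <- probability_histogram(fit, fe, bins = 8)
  tot <- tapply(h$count, h$label, sum)
  expect_equal(unname(tot[["0"]]), sum(fe$binary_label == 0))
  expect_equal(unname(tot[["1"]]), sum(fe$binary_label == 1))
  expect_error(probability_histogram(fit, fe, bins = 1),
               class = "screen_parameter_error")

  # identical scores collapse into a single nonzero bin per label
  fit0 <- manual_fit(c(f1 = 0, f2 = 0), NULL, intercept = 0.3)
  h0 <- probability_histogram(fit0, fe, bins = 5)
  expect_equal(sum(h0$count[h0$label == 1] > 0), 1)
})

test_that("uniform scores spread evenly across bins", {
  set.seed(88)
  n <- 10000
  tbl <- tibble::tibble(subject_id = as.character(1:n),
                        ordinal_label = rep(1L, n),
                        binary_label = rep(1L, n),
                        u = runif(n))
  tbl$binary_label[1] <- 0L  # keep both classes present
  fe <- sparsescreen:::new_screen_features(tbl, 1, rep(60, n))
  fit <- manual_fit(c(u = 1), NULL)
  h <- probability_histogram(fit, fe, bins = 10)
  counts <- h$count[h$label == 1]
  sigma <- sqrt(n * 0.1 * 0.9)
  expect_true(all(abs(counts - n / 10) < 3 * sigma + 1))
})
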