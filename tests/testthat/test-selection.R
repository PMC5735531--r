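# Phase-1 selection: folds, the penalized CV grid search, and the
# one-standard-error rule against a brute-force oracle.

random_parsimony_grid <- function(seed) {
  set.seed(seed)
  grid <- expand.grid(a = sort(10^runif(5, -2, 2)),
                      b = sort(runif(4, 1, 10)))
  parsimony <- c(a = sample(c("high", "low"), 1),
                 b = sample(c("high", "low"), 1))
  n <- nrow(grid)
  objective <- round(runif(n), 2)      # rounding engineers ties
  se <- runif(n, 0.01, 0.1)
  list(grid = grid, objective = objective, se = se, parsimony = parsimony)
}

test_that("stratified folds balance both classes and are seed-stable", {
  y <- c(rep(1, 83), rep(0, 17))
  f <- make_folds(y, 10, seed = 5)
  expect_identical(f, make_folds(y, 10, seed = 5))
  for (k in 1:10) {
    expect_gte(sum(f == k & y == 0), 1)
    expect_lte(abs(sum(f == k & y == 1) - 8.3), 1)
  }
  expect_error(make_folds(c(rep(1, 50), rep(0, 5)), 10),
               class = "screen_cv_error")
})

test_that("one_se_select handles the degenerate and dominance cases", {
  # singleton grid returns its only point
  expect_equal(one_se_select(data.frame(lambda = 1), 0.9, 0.1,
                             c(lambda = "high")), 1)
  # equal objectives: the stronger penalty wins
  expect_equal(one_se_select(data.frame(lambda = c(0.1, 10)),
                             c(0.9, 0.9), c(0.02, 0.02),
                             c(lambda = "high")), 2)
  # a point outside the one-SE band is never chosen
  expect_equal(one_se_select(data.frame(lambda = c(0.1, 10)),
                             c(0.9, 0.5), c(0.01, 0.01),
                             c(lambda = "high")), 1)
})

test_that("one_se_select matches the brute-force oracle on random grids", {
  for (s in 1:200) {
    rg <- random_parsimony_grid(s)
    first <- names(rg$parsimony)[1 + s %% 2]
    got <- one_se_select(rg$grid, rg$objective, rg$se, rg$parsimony,
                         first_axis = first)
    want <- one_se_oracle(rg$grid, rg$objective, rg$se, rg$parsimony, first)
    expect_identical(got, want)
  }
})

test_that("the selected point is never less parsimonious than theta_hat", {
  for (s in 1:50) {
    rg <- random_parsimony_grid(s + 1000)
    hat <- which.max(rg$objective)
    sel <- one_se_select(rg$grid, rg$objective, rg$se, rg$parsimony,
                         first_axis = "a")
    va_hat <- rg$grid$a[hat]
    va_sel <- rg$grid$a[sel]
    if (rg$parsimony[["a"]] == "high") {
      expect_gte(va_sel, va_hat)
    } else {
      expect_lte(va_sel, va_hat)
    }
  }
})

test_that("the SE is the fold-objective standard deviation over sqrt(n)", {
  set.seed(9)
  fold_auc <- matrix(runif(3 * 10, 0.6, 0.95), 3, 10)
  fold_used <- matrix(sample(5:40, 30, replace = TRUE), 3, 10)
  res <- synthetic_selection(data.frame(lambda = c(0.1, 1, 10)),
                             fold_auc, fold_used,
                             c(lambda = "high"), mu = 0.1)
  m_fold <- fold_auc - 0.1 * fold_used / 58
  expect_equal(res$se, apply(m_fold, 1, sd) / sqrt(10))
  expect_equal(res$m_mean, rowMeans(m_fold))
})

test_that("with the penalty off, theta_hat is the plain AUC argmax", {
  fe <- encoded_cohort(n = 200, seed = 20)
  spec <- registry_spec(build_registry(), "lasso")
  res <- run_selection_cv(fe, spec, mu = 0, n_folds = 5, seed = 3)
  expect_equal(res$theta_hat, which.max(rowMeans(res$fold_auc)))
  expect_equal(res$m_mean, res$mean_auc)
})

test_that("increasing mu never increases features used at theta_hat", {
  for (s in 1:30) {
    set.seed(s)
    n_grid <- 8
    fold_auc <- matrix(runif(n_grid * 10, 0.5, 1), n_grid, 10)
    # enforce the lasso-like structure: higher penalty, fewer features
    base_used <- sort(sample(0:58, n_grid, replace = TRUE), decreasing = TRUE)
    fold_used <- base_used + matrix(sample(0:2, n_grid * 10, TRUE),
                                    n_grid, 10)
    fold_used <- pmin(fold_used, 58)
    res <- synthetic_selection(data.frame(lambda = 10^seq(-3, 4)),
                               fold_auc, fold_used, c(lambda = "high"))
    used_at_hat <- vapply(c(0, 0.05, 0.1, 0.3, 1), function(mu) {
      r <- with_penalty(res, mu)
      mean(r$fold_used[r$theta_hat, ])
    }, 0)
    expect_true(all(diff(used_at_hat) <= 1e-12))
  }
})

test_that("a single separating feature is found in nearly every fold", {
  fe <- separable_features(n = 120, seed = 6)
  spec <- registry_spec(build_registry(), "logistic_l1")
  spec$hyper_grid <- list(list(lambda = c(0.001, 0.01, 0.1, 1)))
  res <- run_selection_cv(fe, spec, mu = 0.1, n_folds = 10, seed = 2)
  sets <- res$fold_features[[res$theta_1se]]
  hits <- sum(vapply(sets, function(s) "f1" %in% s, TRUE))
  expect_gte(hits, 9)
})

test_that("selection results are byte-identical under the same seed", {
  fe <- encoded_cohort(n = 150, seed = 21)
  spec <- registry_spec(build_registry(), "elastic_net")
  r1 <- run_selection_cv(fe, spec, mu = 0.1, n_folds = 5, seed = 11)
  r2 <- run_selection_cv(fe, spec, mu = 0.1, n_folds = 5, seed = 11)
  expect_identical(r1, r2)
  r3 <- run_selection_cv(fe, spec, mu = 0.1, n_folds = 5, seed = 12)
  expect_false(identical(r1$fold_auc, r3$fold_auc))
})

test_that("undersampling happens inside training folds only", {
  # validation AUCs must be computed on the full imbalanced folds: the
  # per-fold validation sets together cover every subject exactly once,
  # so per-fold positives sum to the cohort's positive count
  fe <- encoded_cohort(n = 100, seed = 22)
  folds <- make_folds(fe$binary_label, 5, seed = 13)
  expect_equal(sum(table(folds)), nrow(fe))
  spec <- registry_spec(build_registry(), "lasso")
  res <- run_selection_cv(fe, spec, mu = 0.1, n_folds = 5, seed = 13)
  expect_equal(res$n_folds, 5)
  expect_true(all(is.finite(res$fold_auc)))
})

test_that("tidy and glance expose the grid and the selected point", {
  fe <- encoded_cohort(n = 120, seed = 23)
  spec <- registry_spec(build_registry(), "lasso")
  res <- run_selection_cv(fe, spec, mu = 0.1, n_folds = 5, seed = 1)
  td <- tidy(res)
  expect_equal(nrow(td), nrow(res$grid))
  expect_equal(sum(td$is_theta_1se), 1)
  expect_equal(sum(td$is_theta_hat), 1)
  gl <- glance(res)
  expect_equal(gl$m_sparsity, res$m_mean[res$theta_1se])
})
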