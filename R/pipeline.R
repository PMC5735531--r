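# End-to-end convenience wrapper over the three pipeline phases.

#' Run the full two-phase study on a synthetic cohort
#'
#' Convenience driver chaining every stage: simulate (or accept) a
#' cohort, encode features, split 80/20 stratified, run the phase-1
#' L0-penalized selection CV for the chosen configurations, build the
#' regularized and non-regularized heatmaps, derive the reduced-k
#' consensus sets, retune the final classifier on each reduced set
#' (phase 2) and on the full feature set, and evaluate everything on
#' the held-out test partition (phase 3).
#'
#' @param cohort A cohort tibble, or a [cohort_config()] to simulate
#'   from.
#' @param specs Character vector of registry configuration names to
#'   include in phase 1 (default: seven fast sparse linear
#'   configurations spanning three families).
#' @param final_classifier Registry name retrained in phases 2-3.
#' @param k Reduced-set sizes (default 5 and 10).
#' @param mu L0 penalty coefficient for phase 1.
#' @param n_folds Cross-validation folds.
#' @param test_fraction Held-out fraction.
#' @param registry Registry to draw configurations from.
#' @param seed Integer seed driving the split, folds and undersampling.
#' @return A list with elements `features`, `split`, `selections`,
#'   `heatmap_l0`, `heatmap_plain`, `reduced` (one `screen_reduced` per
#'   k), `tunings`, `reports` (one `screen_report` per k plus
#'   `"full"`).
#' @export
screen_pipeline <- function(cohort,
                            specs = c("lasso", "elastic_net",
                                      "relaxed_lasso", "logistic_l1",
                                      "logistic_l2", "lda_shrinkage",
                                      "svm_linear_l1"),
                            final_classifier = "logistic_l2",
                            k = c(5, 10), mu = 0.1, n_folds = 10,
                            test_fraction = 0.2,
                            registry = build_registry(), seed = 1L) {
  if (inherits(cohort, "cohort_config")) cohort <- simulate_cohort(cohort)
  features <- encode_features(cohort)
  split <- stratified_split(features, test_fraction, seed = seed)
  parts <- partition(features, split)

  sel_rows <- registry[registry$name %in% specs, , drop = FALSE]
  selections <- run_selection_many(parts$train, sel_rows, mu = mu,
                                   n_folds = n_folds, seed = seed)
  heatmap_l0 <- build_heatmap(selections, regularized = TRUE)
  heatmap_plain <- build_heatmap(selections, regularized = FALSE)
  reduced <- lapply(k, function(kk) {
    derive_reduced_set(heatmap_l0, heatmap_plain, kk)
  })
  names(reduced) <- paste0("k", k)

  final <- registry_spec(registry, final_classifier)
  eval_set <- function(feats_train, feats_test) {
    tuning <- tune_on_reduced(feats_train, final, n_folds = n_folds,
                              seed = seed)
    fit <- fit_model(final, tuning$hyperparams, feats_train, seed = seed)
    list(tuning = tuning, fit = fit,
         report = evaluate_on_test(fit, feats_test))
  }
  runs <- lapply(reduced, function(r) {
    eval_set(select_features(parts$train, r$features),
             select_features(parts$test, r$features))
  })
  runs$full <- eval_set(parts$train, parts$test)

  list(features = features, split = split, selections = selections,
       heatmap_l0 = heatmap_l0, heatmap_plain = heatmap_plain,
       reduced = reduced,
       tunings = lapply(runs, `[[`, "tuning"),
       fits = lapply(runs, `[[`, "fit"),
       reports = lapply(runs, `[[`, "report"))
}
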