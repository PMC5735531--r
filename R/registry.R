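# Registry of the 17 classifier configurations across 5 families.
#
# Each configuration names its family, feature-selection wrapper,
# hyperparameter grid, the grid axis that controls feature count (the
# "sparsifying" axis), the direction of parsimony on every axis, and
# how class imbalance is handled. Families whose implementations do not
# take observation/class weights (the ordinal regression family and
# nearest shrunken centroids) undersample the majority class to 1:1
# inside each training fold; all others use inverse-frequency class
# weights.
#
# Default grids: penalties on a log scale 10^-3..10^3, tree depth 1-6,
# 10-200 trees, polynomial degree 2-3; wrapper k over a coarse ladder.
# The grids are data, not code: edit the `hyper_grid` list-column (or
# round-trip through YAML) to change them.

PENALTY_GRID <- 10^seq(-3, 3, by = 1)
K_GRID <- c(2, 5, 10, 20, 40)

registry_row <- function(name, family, engine, wrapper, imbalance,
                         ordinal, sparsifier, grid, parsimony,
                         engine_args = list()) {
  tibble::tibble(
    name = name, family = family, engine = engine, wrapper = wrapper,
    imbalance_mode = imbalance, uses_ordinal_target = ordinal,
    sparsifying_param = sparsifier,
    hyper_grid = list(grid), parsimony = list(parsimony),
    engine_args = list(engine_args)
  )
}

#' Build the classifier registry
#'
#' Returns the 17 classifier configurations in five families:
#'
#' * **penalized-linear-regression** (ordinal 0/1/2 target, thresholded
#'   for the binary task; majority class undersampled): plain linear
#'   regression, lasso, ridge, elastic net, relaxed lasso.
#' * **nearest-neighbors** (undersampled): nearest shrunken centroids
#'   with soft-threshold shrinkage.
#' * **general-linear-classifier** (class weights): shrinkage LDA,
#'   L1 and L2 logistic regression.
#' * **support-vector-machine** (class weights): L1-penalized linear
#'   SVM; polynomial, radial and exponential (Laplacian) kernels, the
#'   latter three behind an ANOVA feature-selection wrapper whose `k`
#'   acts as the sparsifying axis.
#' * **tree-based** (class weights): decision tree (depth), random
#'   forest, gradient boosting and AdaBoost (number of trees).
#'
#' For every configuration `parsimony` records, per grid axis, which
#' end is the more parsimonious (larger penalty, smaller k, shallower
#' or fewer trees); the sparsifying axis always ranks first when the
#' one-standard-error rule breaks ties.
#'
#' @return A tibble of class `screen_registry`, one row per
#'   configuration, with list-columns `hyper_grid`, `parsimony` and
#'   `engine_args`.
#' @export
build_registry <- function() {
  rows <- list(
    # -- penalized linear regression family (ordinal target, undersampled)
    registry_row("linear_regression", "penalized-linear-regression",
                 "ols_ordinal", "NS", "undersample", TRUE,
                 "lambda", list(lambda = 0), c(lambda = "high")),
    registry_row("lasso", "penalized-linear-regression",
                 "glmnet_gaussian", "NS", "undersample", TRUE,
                 "lambda", list(lambda = PENALTY_GRID), c(lambda = "high"),
                 engine_args = list(alpha = 1)),
    registry_row("ridge", "penalized-linear-regression",
                 "glmnet_gaussian", "NS", "undersample", TRUE,
                 "lambda", list(lambda = PENALTY_GRID), c(lambda = "high"),
                 engine_args = list(alpha = 0)),
    registry_row("elastic_net", "penalized-linear-regression",
                 "glmnet_gaussian", "NS", "undersample", TRUE,
                 "lambda", list(lambda = PENALTY_GRID, alpha = c(0.2, 0.5, 0.8)),
                 c(lambda = "high", alpha = "high")),
    registry_row("relaxed_lasso", "penalized-linear-regression",
                 "relaxed_lasso", "NS", "undersample", TRUE,
                 "lambda", list(lambda = PENALTY_GRID), c(lambda = "high")),
    # -- nearest neighbors family
    registry_row("nearest_shrunken_centroids", "nearest-neighbors",
                 "nsc", "NS", "undersample", FALSE,
                 "delta", list(delta = c(0, 0.5, 1, 2, 4, 8)),
                 c(delta = "high")),
    # -- general linear classifiers
    registry_row("lda_shrinkage", "general-linear-classifier",
                 "lda_shrinkage", "NS", "class-weights", FALSE,
                 "shrinkage",
                 list(shrinkage = c(0.1, 0.2, 0.4, 0.6, 0.8, 0.95)),
                 c(shrinkage = "high")),
    registry_row("logistic_l1", "general-linear-classifier",
                 "glmnet_binomial", "NS", "class-weights", FALSE,
                 "lambda", list(lambda = PENALTY_GRID), c(lambda = "high"),
                 engine_args = list(alpha = 1)),
    registry_row("logistic_l2", "general-linear-classifier",
                 "glmnet_binomial", "NS", "class-weights", FALSE,
                 "lambda", list(lambda = PENALTY_GRID), c(lambda = "high"),
                 engine_args = list(alpha = 0)),
    # -- support vector machines
    registry_row("svm_linear_l1", "support-vector-machine",
                 "svm_l1", "NS", "class-weights", FALSE,
                 "lambda", list(lambda = PENALTY_GRID), c(lambda = "high")),
    registry_row("svm_polynomial", "support-vector-machine",
                 "svm_kernel", "ANOVA", "class-weights", FALSE,
                 "k", list(k = K_GRID, C = c(0.1, 1, 10), degree = c(2, 3)),
                 c(k = "low", C = "low", degree = "low"),
                 engine_args = list(kernel = "polynomial")),
    registry_row("svm_radial", "support-vector-machine",
                 "svm_kernel", "ANOVA", "class-weights", FALSE,
                 "k", list(k = K_GRID, C = c(0.1, 1, 10)),
                 c(k = "low", C = "low"),
                 engine_args = list(kernel = "radial")),
    registry_row("svm_exponential", "support-vector-machine",
                 "svm_laplace", "ANOVA", "class-weights", FALSE,
                 "k", list(k = K_GRID, C = c(0.1, 1, 10)),
                 c(k = "low", C = "low")),
    # -- tree-based classifiers
    registry_row("decision_tree", "tree-based",
                 "rpart_tree", "NS", "class-weights", FALSE,
                 "maxdepth", list(maxdepth = 1:6), c(maxdepth = "low")),
    registry_row("random_forest", "tree-based",
                 "ranger_rf", "NS", "class-weights", FALSE,
                 "num_trees", list(num_trees = c(10, 25, 50, 100, 200)),
                 c(num_trees = "low")),
    registry_row("gradient_boosting", "tree-based",
                 "xgb_boost", "NS", "class-weights", FALSE,
                 "n_rounds", list(n_rounds = c(10, 25, 50, 100, 200)),
                 c(n_rounds = "low"),
                 engine_args = list(max_depth = 3, eta = 0.3)),
    registry_row("adaboost", "tree-based",
                 "adaboost", "NS", "class-weights", FALSE,
                 "n_trees", list(n_trees = c(10, 25, 50, 100)),
                 c(n_trees = "low"))
  )
  out <- dplyr::bind_rows(rows)
  class(out) <- c("screen_registry", class(out))
  out
}

# One registry row as a plain list (a ModelSpec).
as_spec <- function(spec) {
  if (inherits(spec, "data.frame")) {
    stopifnot(nrow(spec) == 1)
    spec <- lapply(spec, function(col) if (is.list(col)) col[[1]] else col)
  }
  spec
}

#' Look up one configuration by name
#'
#' @param registry A `screen_registry` tibble.
#' @param name Configuration name, e.g. `"logistic_l2"`.
#' @return A one-row registry tibble.
#' @export
registry_spec <- function(registry, name) {
  hit <- registry[registry$name == name, , drop = FALSE]
  if (nrow(hit) != 1) {
    abort(sprintf("unknown classifier configuration '%s'", name),
          class = "screen_input_error")
  }
  hit
}

#' Serialize hyperparameter grids to / from YAML
#'
#' Grids are data: `write_registry_yaml()` dumps each configuration's
#' grid, and `read_registry_yaml()` overlays grids from a YAML file onto
#' a freshly built registry, so runs can be reconfigured without code
#' changes.
#'
#' @param registry A `screen_registry`.
#' @param path YAML file path.
#' @return `read_registry_yaml()` returns the updated registry.
#' @export
write_registry_yaml <- function(registry, path) {
  grids <- setNames(registry$hyper_grid, registry$name)
  yaml::write_yaml(grids, path)
  invisible(registry)
}

#' @rdname write_registry_yaml
#' @export
read_registry_yaml <- function(path, registry = build_registry()) {
  grids <- yaml::read_yaml(path)
  for (nm in names(grids)) {
    i <- which(registry$name == nm)
    if (!length(i)) {
      abort(sprintf("YAML grid for unknown configuration '%s'", nm),
            class = "screen_input_error")
    }
    g <- lapply(grids[[nm]], as.numeric)
    missing_axes <- setdiff(names(registry$parsimony[[i]]), names(g))
    if (length(missing_axes)) {
      abort(sprintf("grid for '%s' lacks axis: %s", nm,
                    paste(missing_axes, collapse = ", ")),
            class = "screen_input_error")
    }
    registry$hyper_grid[[i]] <- g
  }
  registry
}
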