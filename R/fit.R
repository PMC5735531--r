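# Fitting one classifier configuration at one grid point.

#' Fit a classifier configuration
#'
#' Fits one registry configuration at a given hyperparameter setting.
#' Class imbalance is handled per the configuration's `imbalance_mode`:
#' seeded undersampling of the majority class to a 1:1 ratio, or
#' inverse-frequency class weights. If the configuration carries a
#' feature-selection wrapper, the wrapper runs first (on the same data
#' the classifier will see) and the classifier is trained on the
#' selected subset. Regression-family configurations are trained on the
#' ordinal 0/1/2 target but always scored on the binary ASD task.
#'
#' @param spec One registry row ([build_registry()], [registry_spec()]).
#' @param hyperparams Named list drawn from the configuration's grid.
#' @param features Training `screen_features` tibble.
#' @param seed Integer seed for undersampling and any stochastic
#'   engine.
#' @return An object of class `screen_fit`: carries the hyperparameters,
#'   the features handed to the engine (`wrapper_features`), the
#'   features the fitted model actually uses (`features_used`), and a
#'   natural decision threshold. Score new subjects with [predict()];
#'   higher scores mean more ASD-like.
#' @export
fit_model <- function(spec, hyperparams, features, seed = 1L) {
  spec <- as_spec(spec)
  x <- feature_matrix(features)
  ybin <- features$binary_label
  yord <- features$ordinal_label
  if (length(unique(ybin)) < 2) {
    abort("training fold contains a single class; cannot fit",
          class = "screen_fit_error")
  }
  if (spec$imbalance_mode == "undersample") {
    idx <- undersample_index(ybin, child_seed(seed, 23))
    x <- x[idx, , drop = FALSE]
    ybin <- ybin[idx]
    yord <- yord[idx]
  }
  wf <- colnames(x)
  if (spec$wrapper != "NS") {
    wf <- apply_wrapper(x, ybin, spec$wrapper,
                        hyperparams[[spec$sparsifying_param]])
  }
  if (!length(wf)) {
    # totally shrunk wrapper: constant scorer, no features
    eng <- list(model = NULL, features_used = character(), threshold = 0)
    engine <- "constant"
  } else {
    w <- if (spec$imbalance_mode == "class-weights") {
      inverse_freq_weights(ybin)
    } else {
      rep(1, length(ybin))
    }
    engine <- spec$engine
    eng <- engine_fit(engine, x[, wf, drop = FALSE], ybin, yord, w,
                      hyperparams, spec$engine_args, seed)
  }
  structure(
    list(name = spec$name, engine = engine, family = spec$family,
         hyperparams = hyperparams, wrapper_features = wf,
         features_used = eng$features_used,
         model = eng$model, default_threshold = eng$threshold,
         flip = eng$flip %||% 1),
    class = "screen_fit"
  )
}

#' @method predict screen_fit
#' @export
predict.screen_fit <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "screen_features")) {
    feature_matrix(newdata)
  } else {
    as.matrix(newdata)
  }
  if (object$engine == "constant") return(rep(0, nrow(x)))
  engine_score(object, x[, object$wrapper_features, drop = FALSE])
}

#' Number of features a fitted model uses
#'
#' Linear-form models count coefficients whose standardized magnitude
#' exceeds the zero tolerance; tree-based models count features with
#' positive importance or an actual split; wrapped kernel models count
#' the wrapper's selected subset. A base item and its `_missing`
#' indicator count separately.
#'
#' @param fit A `screen_fit`.
#' @return Integer count.
#' @export
count_features_used <- function(fit) {
  length(fit$features_used)
}

#' @method print screen_fit
#' @export
print.screen_fit <- function(x, ...) {
  hp <- paste(names(x$hyperparams), vapply(x$hyperparams, format, ""),
              sep = " = ", collapse = ", ")
  cat(sprintf("<screen_fit> %s (%s)\n  hyperparameters: %s\n  features used: %d\n",
              x$name, x$family, hp, count_features_used(x)))
  invisible(x)
}
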