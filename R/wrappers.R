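# Feature-selection wrappers for classifiers without a built-in
# sparsifying parameter. Each scores features on the training data and
# returns a named subset; the wrapper's own parameter (k, or the lasso
# L1 coefficient) then acts as the sparsifying axis of the grid search.

#' Apply a feature-selection wrapper
#'
#' * `"NS"` — no selection: every feature.
#' * `"ANOVA"` — the `k` features with the largest one-way ANOVA F
#'   statistic between the two classes.
#' * `"Lasso"` — features with nonzero coefficients in an L1-penalized
#'   logistic regression at penalty `param` (inverse-frequency
#'   weighted). May return an empty, degenerate set when the penalty
#'   shrinks everything away.
#' * `"Tree"` — the `k` features ranked most important by a fully grown
#'   decision tree (unused features rank 0; ties broken by column
#'   order).
#'
#' @param x Numeric feature matrix (training fold).
#' @param y Binary labels in `{0, 1}`.
#' @param wrapper One of `"NS"`, `"ANOVA"`, `"Lasso"`, `"Tree"`.
#' @param param Wrapper parameter: `k` for ANOVA/Tree (must not exceed
#'   the feature count), the L1 coefficient (> 0) for Lasso; ignored
#'   for NS.
#' @return Character vector of selected feature names. For the Lasso
#'   wrapper an empty result carries attribute `degenerate = TRUE`.
#' @export
apply_wrapper <- function(x, y, wrapper = c("NS", "ANOVA", "Lasso", "Tree"),
                          param = NULL) {
  wrapper <- match.arg(wrapper)
  p <- ncol(x)
  if (wrapper == "NS") return(colnames(x))
  if (wrapper %in% c("ANOVA", "Tree")) {
    k <- param
    if (is.null(k) || k < 1 || k > p) {
      abort(sprintf("wrapper k must be in 1..%d (got %s)", p,
                    format(param)), class = "screen_parameter_error")
    }
    k <- as.integer(k)
  }
  switch(wrapper,
    ANOVA = {
      f <- anova_f_scores(x, y)
      colnames(x)[order(-f, seq_len(p))[seq_len(k)]]
    },
    Tree = {
      imp <- rep(0, p)
      names(imp) <- colnames(x)
      fit <- rpart_full_tree(x, y)
      vi <- fit$variable.importance
      imp[names(vi)] <- vi
      colnames(x)[order(-imp, seq_len(p))[seq_len(k)]]
    },
    Lasso = {
      if (is.null(param) || param <= 0) {
        abort("Lasso wrapper L1 coefficient must be > 0",
              class = "screen_parameter_error")
      }
      w <- inverse_freq_weights(y)
      fit <- quiet_glmnet(glmnet::glmnet(x, y, family = "binomial",
                                         alpha = 1, weights = w,
                                         lambda = glmnet_path(param)))
      b <- as.numeric(coef(fit, s = param))[-1]
      sel <- colnames(x)[abs(b) > COEF_TOL]
      if (!length(sel)) {
        warn("Lasso wrapper shrank all coefficients to zero (degenerate)")
        attr(sel, "degenerate") <- TRUE
      }
      sel
    }
  )
}

# Vectorized one-way (two-group) ANOVA F statistic per column.
anova_f_scores <- function(x, y) {
  g1 <- y == 1
  n1 <- sum(g1); n0 <- sum(!g1); n <- n1 + n0
  m1 <- colMeans(x[g1, , drop = FALSE])
  m0 <- colMeans(x[!g1, , drop = FALSE])
  m <- colMeans(x)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- colSums((t(t(x[g1, , drop = FALSE]) - m1))^2) +
    colSums((t(t(x[!g1, , drop = FALSE]) - m0))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[is.nan(f)] <- -Inf  # constant columns carry no signal
  f
}

rpart_full_tree <- function(x, y) {
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0, 1))
  rpart::rpart(.y ~ ., data = df, method = "class",
               control = rpart::rpart.control(cp = 0, minsplit = 4,
                                              xval = 0, maxsurrogate = 0))
}

# Lambda path containing the requested penalty: glmnet is meant to be
# fit on a decreasing path, so embed the target in a fixed superset.
glmnet_path <- function(s) {
  sort(unique(c(10^seq(-3, 3, by = 0.5), s)), decreasing = TRUE)
}

# On (near-)separable data the smallest path lambdas of a binomial fit
# routinely hit glmnet's iteration cap while the objective is already
# flat; that path warning is muffled, everything else propagates.
quiet_glmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("Convergence for .*lambda", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}
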