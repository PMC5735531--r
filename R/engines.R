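# Fitting engines behind the classifier registry. Every engine returns
# a list with `model` (whatever the scorer needs), `features_used`
# (feature names given nonzero weight, importance, or a split),
# `threshold` (natural decision cutoff: 0.5 for probability-like
# scores, 0 for margins) and optionally `flip` (+/-1 sign so that
# higher scores always mean more ASD-like).

engine_fit <- function(engine, x, ybin, yord, w, hp, args, seed) {
  hp <- utils::modifyList(args, hp[!vapply(hp, is.null, TRUE)])
  switch(engine,
    ols_ordinal = fit_ols_ordinal(x, yord),
    glmnet_gaussian = fit_glmnet_gaussian(x, yord, hp),
    relaxed_lasso = fit_relaxed_lasso(x, yord, hp),
    nsc = fit_nsc(x, ybin, hp),
    lda_shrinkage = fit_lda_shrinkage(x, ybin, w, hp),
    glmnet_binomial = fit_glmnet_binomial(x, ybin, w, hp),
    svm_l1 = fit_svm_l1(x, ybin, w, hp),
    svm_kernel = fit_svm_kernel(x, ybin, hp),
    svm_laplace = fit_svm_laplace(x, ybin, hp),
    rpart_tree = fit_rpart_tree(x, ybin, w, hp),
    ranger_rf = fit_ranger_rf(x, ybin, hp, seed),
    xgb_boost = fit_xgb_boost(x, ybin, hp, seed),
    adaboost = fit_adaboost(x, ybin, w, hp),
    abort(sprintf("unknown engine '%s'", engine), class = "screen_fit_error")
  )
}

engine_score <- function(fit, x) {
  m <- fit$model
  raw <- switch(fit$engine,
    ols_ordinal = ,
    glmnet_gaussian = ,
    relaxed_lasso = drop(x %*% m$beta) + m$intercept,
    nsc = score_nsc(m, x),
    lda_shrinkage = drop(x %*% m$beta) + m$intercept,
    glmnet_binomial = stats::plogis(drop(x %*% m$beta) + m$intercept),
    svm_l1 = drop(x %*% m$beta) + m$intercept,
    svm_kernel = {
      pr <- predict(m$fit, x, decision.values = TRUE)
      drop(attr(pr, "decision.values"))
    },
    svm_laplace = drop(kernlab::predict(m$fit, x, type = "decision")),
    rpart_tree = predict(m$fit, as.data.frame(x), type = "prob")[, "1"],
    ranger_rf = predict(m$fit, data = x, num.threads = 1)$predictions[, "1"],
    xgb_boost = predict(m$fit, xgboost::xgb.DMatrix(x)),
    adaboost = score_adaboost(m, x),
    abort(sprintf("unknown engine '%s'", fit$engine),
          class = "screen_fit_error")
  )
  unname(as.numeric(raw)) * (fit$flip %||% 1)
}

# Features whose standardized coefficient exceeds the zero tolerance.
nonzero_features <- function(beta, x) {
  sds <- apply(x, 2, sd)
  sds[sds == 0] <- 1
  colnames(x)[abs(beta * sds) > COEF_TOL]
}

# ---- penalized linear regression family (ordinal target) -------------

fit_ols_ordinal <- function(x, yord) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, x), yord)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0  # collinear columns dropped by QR
  list(model = list(beta = beta[-1], intercept = beta[1]),
       features_used = nonzero_features(beta[-1], x), threshold = 0.5)
}

fit_glmnet_gaussian <- function(x, yord, hp) {
  fit <- glmnet::glmnet(x, yord, family = "gaussian",
                        alpha = hp$alpha %||% 0.5,
                        lambda = glmnet_path(hp$lambda))
  b <- as.numeric(coef(fit, s = hp$lambda))
  list(model = list(beta = b[-1], intercept = b[1]),
       features_used = nonzero_features(b[-1], x), threshold = 0.5)
}

fit_relaxed_lasso <- function(x, yord, hp) {
  lasso <- glmnet::glmnet(x, yord, family = "gaussian", alpha = 1,
                          lambda = glmnet_path(hp$lambda))
  b <- as.numeric(coef(lasso, s = hp$lambda))[-1]
  support <- which(abs(b) > COEF_TOL)
  beta <- rep(0, ncol(x))
  names(beta) <- colnames(x)
  if (length(support)) {
    # unpenalized refit on the selected support (lightly ridged
    # only if the reduced design is singular)
    xs <- x[, support, drop = FALSE]
    refit <- stats::lm.fit(cbind(1, xs), yord)
    cf <- refit$coefficients
    if (anyNA(cf)) {
      xa <- cbind(1, xs)
      cf <- solve(crossprod(xa) + 1e-8 * diag(ncol(xa)), crossprod(xa, yord))
    }
    intercept <- cf[1]
    beta[support] <- cf[-1]
  } else {
    intercept <- mean(yord)
  }
  list(model = list(beta = beta, intercept = unname(intercept)),
       features_used = nonzero_features(beta, x), threshold = 0.5)
}

# ---- nearest shrunken centroids --------------------------------------

fit_nsc <- function(x, ybin, hp) {
  classes <- c(0, 1)
  n <- nrow(x)
  nk <- vapply(classes, function(k) sum(ybin == k), 0)
  xbar <- colMeans(x)
  cent <- t(vapply(classes,
                   function(k) colMeans(x[ybin == k, , drop = FALSE]),
                   numeric(ncol(x))))
  ssw <- Reduce(`+`, lapply(seq_along(classes), function(i) {
    xi <- x[ybin == classes[i], , drop = FALSE]
    colSums((t(t(xi) - cent[i, ]))^2)
  }))
  s <- sqrt(ssw / (n - length(classes)))
  s0 <- median(s)
  denom <- s + s0
  mk <- sqrt(1 / nk - 1 / n)
  d <- sweep(sweep(cent, 2, xbar), 2, denom, `/`) / mk
  d_shrunk <- sign(d) * pmax(abs(d) - hp$delta, 0)
  cent_shrunk <- sweep(sweep(d_shrunk * mk, 2, denom, `*`), 2, xbar, `+`)
  used <- colnames(x)[colSums(abs(d_shrunk) > 0) > 0]
  list(model = list(cent = cent_shrunk, denom = denom),
       features_used = used, threshold = 0)
}

# score = discriminant(control) - discriminant(ASD); higher = ASD-like
score_nsc <- function(m, x) {
  delta_k <- function(i) {
    rowSums(sweep(sweep(x, 2, m$cent[i, ]), 2, m$denom, `/`)^2)
  }
  delta_k(1) - delta_k(2)
}

# ---- shrinkage LDA ---------------------------------------------------

fit_lda_shrinkage <- function(x, ybin, w, hp) {
  p <- ncol(x)
  mu <- lapply(c(0, 1), function(k) {
    wk <- w[ybin == k]
    colSums(x[ybin == k, , drop = FALSE] * wk) / sum(wk)
  })
  centered <- x
  centered[ybin == 0, ] <- sweep(x[ybin == 0, , drop = FALSE], 2, mu[[1]])
  centered[ybin == 1, ] <- sweep(x[ybin == 1, , drop = FALSE], 2, mu[[2]])
  S <- crossprod(centered * sqrt(w)) / sum(w)
  tr <- sum(diag(S))
  if (tr == 0) {
    return(list(model = list(beta = rep(0, p), intercept = 0),
                features_used = character(), threshold = 0))
  }
  Ss <- (1 - hp$shrinkage) * S + hp$shrinkage * (tr / p) * diag(p)
  beta <- solve(Ss, mu[[2]] - mu[[1]])
  intercept <- -sum(beta * (mu[[1]] + mu[[2]])) / 2
  list(model = list(beta = as.numeric(beta), intercept = intercept),
       features_used = nonzero_features(as.numeric(beta), x), threshold = 0)
}

# ---- logistic regression ---------------------------------------------

fit_glmnet_binomial <- function(x, ybin, w, hp) {
  fit <- quiet_glmnet(glmnet::glmnet(x, ybin, family = "binomial",
                                     alpha = hp$alpha %||% 1, weights = w,
                                     lambda = glmnet_path(hp$lambda)))
  b <- as.numeric(coef(fit, s = hp$lambda))
  list(model = list(beta = b[-1], intercept = b[1]),
       features_used = nonzero_features(b[-1], x), threshold = 0.5)
}

# ---- L1-penalized linear SVM (squared hinge, FISTA) ------------------
# minimize (1/n) sum_i w_i max(0, 1 - z_i f(x_i))^2 + lambda ||beta||_1
# on standardized features; no installed package provides an
# L1-penalized linear SVM, so the solver is implemented here.

fit_svm_l1 <- function(x, ybin, w, hp, max_iter = 1000, tol = 1e-9) {
  z <- 2 * ybin - 1
  n <- nrow(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  lambda <- hp$lambda

  smooth_loss <- function(beta, b) {
    a <- pmax(0, 1 - z * (drop(xs %*% beta) + b))
    sum(w * a^2) / n
  }
  gradient <- function(beta, b) {
    a <- pmax(0, 1 - z * (drop(xs %*% beta) + b))
    g <- -2 * w * a * z / n
    list(beta = drop(crossprod(xs, g)), b = sum(g))
  }
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

  beta <- beta_y <- rep(0, ncol(x))
  b <- b_y <- 0
  tk <- 1
  L <- 1
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    g <- gradient(beta_y, b_y)
    f_y <- smooth_loss(beta_y, b_y)
    repeat {
      beta_new <- soft(beta_y - g$beta / L, lambda / L)
      b_new <- b_y - g$b / L
      db <- beta_new - beta_y
      dbb <- b_new - b_y
      quad <- f_y + sum(g$beta * db) + g$b * dbb +
        L / 2 * (sum(db^2) + dbb^2)
      if (smooth_loss(beta_new, b_new) <= quad + 1e-12 || L > 1e12) break
      L <- L * 2
    }
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    beta_y <- beta_new + (tk - 1) / tk_new * (beta_new - beta)
    b_y <- b_new + (tk - 1) / tk_new * (b_new - b)
    beta <- beta_new
    b <- b_new
    tk <- tk_new
    obj <- smooth_loss(beta, b) + lambda * sum(abs(beta))
    if (abs(obj_old - obj) < tol * max(1, abs(obj_old))) break
    obj_old <- obj
  }
  used <- colnames(x)[abs(beta) > COEF_TOL]
  beta_orig <- beta / scl
  intercept <- b - sum(beta_orig * ctr)
  list(model = list(beta = beta_orig, intercept = intercept),
       features_used = used, threshold = 0)
}

# ---- kernel SVMs -----------------------------------------------------

svm_class_weights <- function(ybin) {
  n <- length(ybin)
  setNames(n / (2 * c(sum(ybin == 0), sum(ybin == 1))), c("0", "1"))
}

# Orient a decision score so higher = ASD; deterministic.
decision_flip <- function(dv, ybin) {
  if (mean(dv[ybin == 1]) >= mean(dv[ybin == 0])) 1 else -1
}

fit_svm_kernel <- function(x, ybin, hp) {
  yf <- factor(ybin, levels = c(0, 1))
  fit <- e1071::svm(x, yf, kernel = hp$kernel %||% "radial",
                    cost = hp$C, degree = hp$degree %||% 3,
                    gamma = 1 / ncol(x), coef0 = 1,
                    class.weights = svm_class_weights(ybin),
                    scale = FALSE)
  dv <- drop(attr(predict(fit, x, decision.values = TRUE),
                  "decision.values"))
  list(model = list(fit = fit), features_used = colnames(x),
       threshold = 0, flip = decision_flip(dv, ybin))
}

fit_svm_laplace <- function(x, ybin, hp) {
  yf <- factor(ybin, levels = c(0, 1))
  fit <- kernlab::ksvm(x, yf, kernel = "laplacedot",
                       kpar = list(sigma = 1 / ncol(x)), C = hp$C,
                       class.weights = svm_class_weights(ybin),
                       scaled = FALSE, prob.model = FALSE)
  dv <- drop(kernlab::predict(fit, x, type = "decision"))
  list(model = list(fit = fit), features_used = colnames(x),
       threshold = 0, flip = decision_flip(dv, ybin))
}

# ---- tree-based classifiers ------------------------------------------

tree_split_vars <- function(fit) {
  setdiff(unique(as.character(fit$frame$var)), "<leaf>")
}

fit_rpart_tree <- function(x, ybin, w, hp) {
  df <- as.data.frame(x)
  df$.y <- factor(ybin, levels = c(0, 1))
  ctrl <- rpart::rpart.control(maxdepth = hp$maxdepth, cp = 0,
                               minsplit = 8, minbucket = 4, xval = 0,
                               maxsurrogate = 0)
  fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                      control = ctrl)
  list(model = list(fit = fit), features_used = tree_split_vars(fit),
       threshold = 0.5)
}

fit_ranger_rf <- function(x, ybin, hp, seed) {
  yf <- factor(ybin, levels = c(0, 1))
  n <- length(ybin)
  cw <- n / (2 * c(sum(ybin == 0), sum(ybin == 1)))
  fit <- ranger::ranger(x = x, y = yf, probability = TRUE,
                        num.trees = hp$num_trees,
                        class.weights = cw, seed = seed,
                        num.threads = 1, importance = "impurity")
  imp <- fit$variable.importance
  list(model = list(fit = fit),
       features_used = names(imp)[imp > COEF_TOL], threshold = 0.5)
}

fit_xgb_boost <- function(x, ybin, hp, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = ybin)
  params <- list(objective = "binary:logistic",
                 max_depth = hp$max_depth %||% 3,
                 eta = hp$eta %||% 0.3, nthread = 1,
                 scale_pos_weight = sum(ybin == 0) / sum(ybin == 1))
  fit <- xgboost::xgb.train(params, dtrain, nrounds = hp$n_rounds,
                            verbose = 0)
  imp <- tryCatch(xgboost::xgb.importance(model = fit),
                  error = function(e) NULL)
  used <- if (is.null(imp) || nrow(imp) == 0) character() else imp$Feature
  list(model = list(fit = fit), features_used = used, threshold = 0.5)
}

# SAMME AdaBoost over depth-1 rpart stumps; observation weights start
# at the inverse-frequency class weights so imbalance is handled the
# same way as for the other weighted classifiers.
fit_adaboost <- function(x, ybin, w, hp) {
  df <- as.data.frame(x)
  df$.y <- factor(ybin, levels = c(0, 1))
  n <- nrow(df)
  wt <- w / sum(w)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = 0, minsplit = 2,
                               minbucket = 1, xval = 0, maxsurrogate = 0)
  stumps <- list()
  alpha <- numeric()
  for (t in seq_len(hp$n_trees)) {
    stump <- rpart::rpart(.y ~ ., data = df, weights = wt * n,
                          method = "class", control = ctrl)
    pred <- predict(stump, df, type = "class")
    mis <- pred != df$.y
    err <- sum(wt * mis)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    a <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- stump
    alpha <- c(alpha, a)
    wt <- wt * exp(a * ifelse(mis, 1, -1))
    wt <- wt / sum(wt)
  }
  used <- unique(unlist(lapply(stumps, tree_split_vars)))
  list(model = list(stumps = stumps, alpha = alpha),
       features_used = used %||% character(), threshold = 0)
}

score_adaboost <- function(m, x) {
  if (!length(m$stumps)) return(rep(0, nrow(x)))
  df <- as.data.frame(x)
  votes <- vapply(seq_along(m$stumps), function(t) {
    cl <- predict(m$stumps[[t]], df, type = "class")
    m$alpha[t] * (2 * (cl == "1") - 1)
  }, numeric(nrow(x)))
  rowSums(matrix(votes, nrow = nrow(x)))
}
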