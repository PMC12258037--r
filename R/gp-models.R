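#' GBLUP fit-and-predict
#'
#' Genomic BLUP from the mixed-model formulas: the VanRaden relationship
#' matrix G is built on the stacked train+test dosage rows, the variance
#' ratio `delta = s2_e / s2_g` is REML-estimated on the training block
#' ([reml_null()]), the intercept is the generalized-least-squares mean, and
#' test genetic values are `G_test,train (G_train,train + delta I)^-1
#' (y_train - mu)`. Under the VanRaden scaling this equals ridge regression
#' on centered dosages with penalty `lambda = delta * 2 * sum(p (1 - p))`.
#'
#' @param X_train,X_test Dosage matrices (lines x markers, same columns).
#' @param y_train Training phenotypes.
#' @param delta Optional fixed variance ratio; default REML on the training
#'   block.
#' @return Numeric predictions for the test lines.
#' @export
gblup_fit_predict <- function(X_train, y_train, X_test, delta = NULL) {
  stopifnot(ncol(X_train) == ncol(X_test), nrow(X_train) == length(y_train))
  if (nrow(X_train) < 2) abort("need >= 2 training lines")
  n_tr <- nrow(X_train)
  G <- vanraden_grm(rbind(X_train, X_test))
  Gtr <- G[seq_len(n_tr), seq_len(n_tr), drop = FALSE]
  Gte <- G[-seq_len(n_tr), seq_len(n_tr), drop = FALSE]
  if (is.null(delta)) {
    delta <- reml_null(y_train, Gtr)$delta
  }
  V <- Gtr + diag(delta, n_tr)
  Vi1 <- solve(V, rep(1, n_tr))
  mu <- sum(Vi1 * y_train) / sum(Vi1)
  alpha <- solve(V, y_train - mu)
  drop(mu + Gte %*% alpha)
}

#' Bayesian Lasso fit-and-predict
#'
#' Park & Casella (2008) hierarchy sampled by Gibbs (double-exponential
#' prior on marker effects via per-marker scale mixtures; the shrinkage
#' parameter `lambda^2` carries a Gamma(r, rho) hyperprior). Features are
#' centered internally; predictions are `mu + X_test beta` at the posterior
#' means after burn-in. A single chain, reproducible per seed.
#'
#' @param X_train,X_test Feature matrices with matching columns.
#' @param y_train Training phenotypes.
#' @param n_iter Total Gibbs iterations (default 3000).
#' @param burn_in Discarded iterations (default 500).
#' @param r_hyper,rho_hyper Gamma hyperprior on `lambda^2` (weakly
#'   informative defaults 1 and 0.1).
#' @param seed RNG seed.
#' @param details Also return posterior-mean effects and chains.
#' @return Predictions, or (with `details`) a list `pred`, `mu`, `beta`,
#'   `lambda2_chain`, `sigma2_chain`.
#' @export
bayes_lasso_fit_predict <- function(X_train, y_train, X_test, n_iter = 3000L,
                                    burn_in = 500L, r_hyper = 1,
                                    rho_hyper = 0.1, seed = 1L,
                                    details = FALSE) {
  stopifnot(ncol(X_train) == ncol(X_test), nrow(X_train) == length(y_train))
  if (n_iter <= burn_in) abort("`n_iter` must exceed `burn_in`")
  if (stats::var(y_train) == 0) abort("zero-variance response")
  ctr <- colMeans(X_train)
  Xc <- sweep(X_train, 2, ctr, `-`)
  fit <- with_seed(seed, .bl_gibbs(Xc, y_train, as.integer(n_iter),
                                   as.integer(burn_in), r_hyper, rho_hyper))
  Xt <- sweep(X_test, 2, ctr, `-`)
  pred <- drop(fit$mu + Xt %*% fit$beta)
  if (!details) return(pred)
  list(pred = pred, mu = fit$mu, beta = drop(fit$beta),
       lambda2_chain = fit$lambda2, sigma2_chain = fit$sigma2)
}

#' Kernel ridge regression fit-and-predict
#'
#' RBF kernel `k(x, x') = exp(-gamma ||x - x'||^2)`; dual coefficients
#' `alpha = (K + c I)^-1 (y - ybar)`; predictions `ybar + K_test alpha`.
#' Columns are standardized on the training statistics.
#'
#' @param X_train,X_test Feature matrices.
#' @param y_train Training phenotypes.
#' @param c Regularization (> 0; study range 1-500).
#' @param gamma RBF bandwidth (> 0; study range 1e-5 to 1e-3).
#' @param standardize Standardize columns by training mean/SD (default).
#' @return Predictions for the test rows.
#' @export
krr_fit_predict <- function(X_train, y_train, X_test, c = 1, gamma = 1e-4,
                            standardize = TRUE) {
  stopifnot(ncol(X_train) == ncol(X_test))
  if (c <= 0 || gamma <= 0) abort("`c` and `gamma` must be > 0")
  if (standardize) {
    mu <- colMeans(X_train)
    sdv <- apply(X_train, 2, stats::sd)
    sdv[sdv == 0] <- 1
    X_train <- sweep(sweep(X_train, 2, mu, `-`), 2, sdv, `/`)
    X_test <- sweep(sweep(X_test, 2, mu, `-`), 2, sdv, `/`)
  }
  sq_tr <- rowSums(X_train^2)
  K <- exp(-gamma * outer(sq_tr, sq_tr, `+`) +
             2 * gamma * tcrossprod(X_train))
  if (any(!is.finite(K))) abort("non-finite kernel entries")
  ybar <- mean(y_train)
  alpha <- solve(K + diag(c, nrow(K)), y_train - ybar)
  Kte <- exp(-gamma * outer(rowSums(X_test^2), sq_tr, `+`) +
               2 * gamma * tcrossprod(X_test, X_train))
  drop(ybar + Kte %*% alpha)
}

#' Random-forest fit-and-predict
#'
#' Bootstrap-aggregated CART regression via the ranger engine, single thread
#' for per-seed reproducibility.
#'
#' @param X_train,X_test Feature matrices.
#' @param y_train Training phenotypes.
#' @param n_trees Trees in the forest.
#' @param max_depth Maximum tree depth (0 = unlimited).
#' @param mtry Variables per split (default: ranger's sqrt rule).
#' @param seed RNG seed.
#' @param ... Further arguments passed to [ranger::ranger()] (e.g.
#'   `replace`, `sample.fraction`).
#' @return Predictions for the test rows.
#' @export
rf_fit_predict <- function(X_train, y_train, X_test, n_trees = 100L,
                           max_depth = 0L, mtry = NULL, seed = 1L, ...) {
  if (ncol(X_train) == 0) abort("empty feature matrix")
  assert_count(n_trees, "n_trees")
  d_tr <- as.data.frame(X_train)
  names(d_tr) <- sprintf("f%d", seq_len(ncol(X_train)))
  d_te <- as.data.frame(X_test)
  names(d_te) <- names(d_tr)
  d_tr$.y <- y_train
  fit <- ranger::ranger(
    .y ~ ., data = d_tr,
    num.trees = n_trees, max.depth = max_depth,
    mtry = mtry, seed = as.integer(seed), num.threads = 1, ...
  )
  stats::predict(fit, data = d_te, num.threads = 1)$predictions
}

#' Gradient-boosted regression trees fit-and-predict
#'
#' Stage-wise squared-error boosting (`F_0 = ybar`, `F_t = F_{t-1} +
#' lr * tree(residuals)`) backed by the xgboost engine with unpenalized
#' exact-greedy trees, run single threaded so runs are reproducible per
#' seed. The `preset` argument switches between depth-wise ("gbdt",
#' "xgboost") and a shallower leaf-limited profile ("lightgbm"), mirroring
#' common boosting system defaults behind one contract.
#'
#' @param X_train,X_test Feature matrices.
#' @param y_train Training phenotypes.
#' @param n_trees Boosting rounds (study range 20-200).
#' @param max_depth Depth of each weak learner (study range 5-25; xgboost
#'   caps usable depth well above this).
#' @param learning_rate Shrinkage in (0, 1\] (study range 0.01-0.1).
#' @param preset `"gbdt"`, `"xgboost"` or `"lightgbm"`.
#' @param seed RNG seed.
#' @return Predictions for the test rows.
#' @export
gbdt_fit_predict <- function(X_train, y_train, X_test, n_trees = 100L,
                             max_depth = 6L, learning_rate = 0.1,
                             preset = c("gbdt", "xgboost", "lightgbm"),
                             seed = 1L) {
  preset <- match.arg(preset)
  if (learning_rate <= 0 || learning_rate > 1) {
    abort("`learning_rate` must lie in (0, 1]")
  }
  assert_count(n_trees, "n_trees")
  y_train <- as.numeric(y_train)  # strip names/dim: xgboost rejects 1-d arrays
  ybar <- mean(y_train)
  params <- list(
    objective = "reg:squarederror", eta = learning_rate,
    max_depth = as.integer(max_depth), lambda = 0, alpha = 0,
    min_child_weight = 1, subsample = 1, colsample_bytree = 1,
    base_score = ybar, nthread = 1, tree_method = "exact",
    seed = as.integer(seed)
  )
  if (preset == "lightgbm") {
    params$grow_policy <- "lossguide"
    params$max_leaves <- 31L
    params$tree_method <- "hist"
  }
  dtr <- xgboost::xgb.DMatrix(data = unname(as.matrix(X_train)),
                              label = y_train, nthread = 1)
  fit <- xgboost::xgb.train(params = params, data = dtr,
                            nrounds = as.integer(n_trees), verbose = 0)
  stats::predict(fit, unname(as.matrix(X_test)))
}

# ---- model registry ---------------------------------------------------------

#' Prediction-model registry
#'
#' Bundles a model name and hyperparameters into a spec usable by
#' [cross_validate()] and [benchmark_grid()]. Recognized names: `"GBLUP"`,
#' `"BayesLasso"`, `"KRR"`, `"RF"`, `"GBDT"`, `"XGBoost"`, `"LightGBM"`
#' (the last three are presets of one boosted-tree regressor).
#'
#' @param name Model name.
#' @param ... Hyperparameters passed to the underlying `*_fit_predict`.
#' @param seed RNG seed for stochastic models.
#' @return Object of class `gp_model_spec`.
#' @export
gp_model <- function(name, ..., seed = 1L) {
  known <- c("GBLUP", "BayesLasso", "KRR", "RF", "GBDT", "XGBoost", "LightGBM")
  if (!name %in% known) {
    abort(sprintf("unknown model '%s' (known: %s)", name,
                  paste(known, collapse = ", ")))
  }
  structure(list(name = name, params = list(...), seed = as.integer(seed)),
            class = "gp_model_spec")
}

#' @export
print.gp_model_spec <- function(x, ...) {
  ps <- if (length(x$params) == 0) "defaults" else
    paste(names(x$params), vapply(x$params, format, character(1)),
          sep = "=", collapse = ", ")
  cat(sprintf("<gp_model_spec> %s (%s)\n", x$name, ps))
  invisible(x)
}

# dispatch a spec to its fit-predict backend
fit_predict <- function(spec, X_train, y_train, X_test) {
  stopifnot(inherits(spec, "gp_model_spec"))
  if (ncol(X_train) == 0) abort("empty feature matrix")
  p <- spec$params
  switch(
    spec$name,
    GBLUP = do.call(gblup_fit_predict,
                    c(list(X_train, y_train, X_test), p)),
    BayesLasso = do.call(bayes_lasso_fit_predict,
                         c(list(X_train, y_train, X_test), p,
                           list(seed = spec$seed))),
    KRR = do.call(krr_fit_predict, c(list(X_train, y_train, X_test), p)),
    RF = do.call(rf_fit_predict,
                 c(list(X_train, y_train, X_test), p, list(seed = spec$seed))),
    GBDT = do.call(gbdt_fit_predict,
                   c(list(X_train, y_train, X_test), p,
                     list(preset = "gbdt", seed = spec$seed))),
    XGBoost = do.call(gbdt_fit_predict,
                      c(list(X_train, y_train, X_test), p,
                        list(preset = "xgboost", seed = spec$seed))),
    LightGBM = do.call(gbdt_fit_predict,
                       c(list(X_train, y_train, X_test), p,
                         list(preset = "lightgbm", seed = spec$seed)))
  )
}
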