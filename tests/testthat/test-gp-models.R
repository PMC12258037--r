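sim_xy <- function(n = 120, m = 300, n_test = 30, h2 = 0.6, seed = 1) {
  g <- iid_geno(n + n_test, m, seed = seed)
  v <- iid_variants(g)
  tr <- plant_qtl(g, v, 3, 40, h2 = h2, year_effect_sd = 0, seed = seed + 1)
  ph <- simulate_phenotypes(g, tr, n_years = 1, n_reps = 1, seed = seed + 2)
  y <- line_means(ph, g)
  list(Xtr = g[1:n, , drop = FALSE], ytr = y[1:n],
       Xte = g[(n + 1):(n + n_test), , drop = FALSE], yte = y[(n + 1):(n + n_test)],
       g = g, truth = tr)
}

test_that("GBLUP equals the marker-ridge oracle under the VanRaden mapping", {
  d <- sim_xy(seed = 11)
  pred <- gblup_fit_predict(d$Xtr, d$ytr, d$Xte)
  # independent primal ridge oracle with the mapped penalty
  X <- rbind(d$Xtr, d$Xte)
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  Z <- sweep(X[, keep], 2, 2 * p[keep], `-`)
  denom <- 2 * sum(p[keep] * (1 - p[keep]))
  Gtr <- tcrossprod(Z[1:120, ]) / denom
  vc <- reml_null(d$ytr, Gtr)
  V <- Gtr + diag(vc$delta, 120)
  Vi1 <- solve(V, rep(1, 120))
  mu <- sum(Vi1 * d$ytr) / sum(Vi1)
  beta <- solve(crossprod(Z[1:120, ]) + diag(vc$delta * denom, ncol(Z)),
                crossprod(Z[1:120, ], d$ytr - mu))
  oracle <- mu + drop(Z[121:150, ] %*% beta)
  expect_lt(max(abs(pred - oracle)) / sd(d$ytr), 1e-6)
})

test_that("infinite shrinkage collapses GBLUP to the GLS mean", {
  d <- sim_xy(seed = 12)
  pred <- gblup_fit_predict(d$Xtr, d$ytr, d$Xte, delta = 1e10)
  expect_lt(diff(range(pred)) / sd(d$ytr), 1e-6)
})

test_that("a duplicated training line is nearly interpolated at small delta", {
  d <- sim_xy(seed = 13)
  Xte <- rbind(d$Xtr[5, , drop = FALSE])
  rownames(Xte) <- "copy"
  pred <- gblup_fit_predict(d$Xtr, d$ytr, Xte, delta = 1e-4)
  expect_lt(abs(pred - d$ytr[5]), 0.05 * sd(d$ytr))
})

test_that("Bayesian Lasso shrinks null effects toward zero", {
  # on null traits the posterior means must sit well inside the marginal
  # least-squares effects (the unshrunk reference)
  shrunk <- vapply(1:20, function(s) {
    g <- iid_geno(200, 500, seed = 4000 + s)
    y <- withr::with_seed(s, rnorm(200))
    fit <- bayes_lasso_fit_predict(g, y, g[1:2, , drop = FALSE],
                                   n_iter = 600, burn_in = 200, seed = s,
                                   details = TRUE)
    gc <- sweep(g, 2, colMeans(g))
    ols <- drop(crossprod(gc, y - mean(y))) / colSums(gc^2)
    median(abs(fit$beta)) < 0.5 * median(abs(ols))
  }, logical(1))
  expect_gte(sum(shrunk), 18)
})

test_that("a forced-huge shrinkage parameter degenerates to the intercept", {
  d <- sim_xy(n = 80, m = 200, seed = 19)
  fit <- bayes_lasso_fit_predict(d$Xtr, d$ytr, d$Xte, n_iter = 500,
                                 burn_in = 100, r_hyper = 1e8,
                                 rho_hyper = 1, seed = 3, details = TRUE)
  expect_lt(max(abs(fit$beta)), 1e-2)
  expect_lt(max(abs(fit$pred - mean(d$ytr))) / sd(d$ytr), 0.1)
})

test_that("Bayesian Lasso is seed-reproducible and location-equivariant", {
  d <- sim_xy(n = 80, m = 200, seed = 14)
  p1 <- bayes_lasso_fit_predict(d$Xtr, d$ytr, d$Xte, n_iter = 500,
                                burn_in = 100, seed = 9)
  p2 <- bayes_lasso_fit_predict(d$Xtr, d$ytr, d$Xte, n_iter = 500,
                                burn_in = 100, seed = 9)
  expect_identical(p1, p2)
  p3 <- bayes_lasso_fit_predict(d$Xtr, d$ytr + 100, d$Xte, n_iter = 500,
                                burn_in = 100, seed = 9)
  expect_equal(p3, p1 + 100, tolerance = 1e-6)
  expect_error(bayes_lasso_fit_predict(d$Xtr, rep(1, nrow(d$Xtr)), d$Xte),
               "zero-variance")
  expect_error(bayes_lasso_fit_predict(d$Xtr, d$ytr, d$Xte, n_iter = 10,
                                       burn_in = 20), "exceed")
})

test_that("KRR limits and closed form behave", {
  d <- sim_xy(n = 60, m = 100, seed = 15)
  # gamma -> 0: constant kernel, predictions near the training mean
  p0 <- krr_fit_predict(d$Xtr, d$ytr, d$Xte, c = 1, gamma = 1e-12)
  expect_lt(max(abs(p0 - mean(d$ytr))) / sd(d$ytr), 1e-3)
  # huge regularization: total shrinkage
  p1 <- krr_fit_predict(d$Xtr, d$ytr, d$Xte, c = 1e6, gamma = 1e-4)
  expect_lt(max(abs(p1 - mean(d$ytr))) / sd(d$ytr), 1e-3)
  expect_error(krr_fit_predict(d$Xtr, d$ytr, d$Xte, c = -1), "> 0")
  # 5-point 1-D toy set against a hand-assembled dual solve
  xt <- matrix(c(0, 1, 2, 3, 4), ncol = 1)
  yt <- c(0, 1, 0, 2, 1)
  xs <- matrix(c(0.5, 2.5), ncol = 1)
  K <- exp(-0.5 * outer(xt[, 1], xt[, 1], `-`)^2)
  alpha <- solve(K + diag(1, 5), yt - mean(yt))
  Ks <- exp(-0.5 * outer(xs[, 1], xt[, 1], `-`)^2)
  oracle <- mean(yt) + drop(Ks %*% alpha)
  got <- krr_fit_predict(xt, yt, xs, c = 1, gamma = 0.5, standardize = FALSE)
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("random forest leaf means and constancy limits hold", {
  x <- matrix(rep(c(0, 2), each = 20), ncol = 1)
  rownames(x) <- sprintf("L%d", 1:40); colnames(x) <- "m1"
  y <- c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1))
  pred <- rf_fit_predict(x, y, x, n_trees = 1, max_depth = 1, mtry = 1,
                         seed = 1, replace = FALSE, sample.fraction = 1)
  expect_equal(unique(round(pred, 6)),
               round(c(mean(y[1:20]), mean(y[21:40])), 6))
  yc <- rep(3, 40)
  expect_equal(rf_fit_predict(x, yc, x, n_trees = 5, seed = 1),
               rep(3, 40))
  expect_error(rf_fit_predict(x[, 0, drop = FALSE], y, x[, 0, drop = FALSE]),
               "empty")
})

test_that("forest training error drops as trees accumulate", {
  better <- vapply(1:10, function(s) {
    d <- sim_xy(n = 80, m = 60, n_test = 10, seed = 5000 + s)
    e5 <- mean((rf_fit_predict(d$Xtr, d$ytr, d$Xtr, n_trees = 5,
                               seed = s) - d$ytr)^2)
    e50 <- mean((rf_fit_predict(d$Xtr, d$ytr, d$Xtr, n_trees = 50,
                                seed = s) - d$ytr)^2)
    e50 < e5
  }, logical(1))
  expect_gte(sum(better), 9)
})

test_that("boosting limits, consistency on a staircase, and determinism", {
  d <- sim_xy(n = 60, m = 50, seed = 16)
  p0 <- gbdt_fit_predict(d$Xtr, d$ytr, d$Xte, n_trees = 1,
                         learning_rate = 0.01)
  expect_lt(max(abs(p0 - mean(d$ytr))) / sd(d$ytr), 0.1)
  # 1-D staircase fits to numerical zero with depth-1 learners
  x <- matrix(sort(rep(1:4, 10)) + 0.0, ncol = 1)
  rownames(x) <- sprintf("L%d", 1:40); colnames(x) <- "m1"
  y <- as.numeric(x[, 1] %% 2 == 0) * 2 + x[, 1]
  fitted <- gbdt_fit_predict(x, y, x, n_trees = 300, max_depth = 1,
                             learning_rate = 0.3)
  expect_lt(mean((fitted - y)^2), 1e-3 * var(y))
  expect_identical(
    gbdt_fit_predict(d$Xtr, d$ytr, d$Xte, n_trees = 30, seed = 4),
    gbdt_fit_predict(d$Xtr, d$ytr, d$Xte, n_trees = 30, seed = 4)
  )
  expect_error(gbdt_fit_predict(d$Xtr, d$ytr, d$Xte, learning_rate = 0),
               "learning_rate")
})

test_that("all registry models are location-equivariant", {
  d <- sim_xy(n = 60, m = 80, n_test = 15, seed = 17)
  shift <- 42
  for (name in c("GBLUP", "KRR", "GBDT", "XGBoost", "LightGBM", "RF")) {
    spec <- gp_model(name, seed = 3)
    p0 <- gwaspred:::fit_predict(spec, d$Xtr, d$ytr, d$Xte)
    p1 <- gwaspred:::fit_predict(spec, d$Xtr, d$ytr + shift, d$Xte)
    # tree engines reproduce the shift up to split tie-breaks that can flip
    # under floating-point translation of the response
    tol <- if (name %in% c("GBLUP", "KRR")) 1e-8 else 5e-3
    expect_equal(mean(p1 - p0), shift, tolerance = tol,
                 label = sprintf("%s mean shift", name))
    expect_gt(cor(p1 - shift, p0), 0.999)
  }
})

test_that("the registry rejects unknown models and empty features", {
  expect_error(gp_model("SVM"), "unknown model")
  d <- sim_xy(n = 30, m = 60, n_test = 5, seed = 18)
  expect_error(gwaspred:::fit_predict(gp_model("GBLUP"),
                                      d$Xtr[, 0], d$ytr, d$Xte[, 0]),
               "empty")
})
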