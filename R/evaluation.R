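#' Shuffled k-fold assignment
#'
#' Partitions `n` items into `k` folds whose sizes differ by at most one;
#' deterministic per seed.
#'
#' @param n Number of items.
#' @param k Folds (default 10).
#' @param seed RNG seed.
#' @return Integer vector of fold labels in `1..k`.
#' @export
kfold_split <- function(n, k = 10L, seed = 1L) {
  assert_count(n, "n"); assert_count(k, "k")
  if (k > n) abort("`k` cannot exceed `n`")
  with_seed(seed, {
    sample(rep_len(seq_len(k), n))
  })
}

#' Pearson prediction accuracy
#'
#' Standard Pearson correlation between observed and predicted values; `NA`
#' when either vector has zero variance or fewer than three finite pairs.
#'
#' @param y_true,y_pred Numeric vectors.
#' @return Correlation in \[-1, 1\] or `NA`.
#' @export
pearson_accuracy <- function(y_true, y_pred) pearson_r(y_true, y_pred)

#' k-fold cross-validated prediction accuracy
#'
#' Fits the model on each training fold and scores Pearson accuracy on the
#' held-out lines. `features` is either a [threshold_features()]-style
#' `feature_set` / plain matrix (the whole-panel mode, which reproduces
#' pipelines that select markers on the full panel before CV and therefore
#' leaks selection information into the folds) or a function
#' `function(train_idx) -> feature_set` re-selecting features inside each
#' training fold (the leakage-free mode).
#'
#' @param features `feature_set`, matrix, or selector function of the
#'   training index vector.
#' @param y Phenotype vector (one value per line, panel order).
#' @param model A [gp_model()] spec.
#' @param k Folds (default 10).
#' @param seed Seed for the fold split.
#' @return Object of class `cv_report`: `per_fold` tibble
#'   (`fold, n_test, r`), `mean_r`, `sd_r`, `folds` assignment, `model`,
#'   `provenance`.
#' @export
cross_validate <- function(features, y, model, k = 10L, seed = 1L) {
  stopifnot(inherits(model, "gp_model_spec"))
  n <- length(y)
  folds <- kfold_split(n, k, seed)
  selector <- NULL
  if (is.function(features)) {
    selector <- features
    prov <- list(kind = "within_fold_selector")
  } else {
    X <- if (inherits(features, "feature_set")) features$matrix else features
    if (nrow(X) != n) abort("feature rows are not aligned to `y`")
    prov <- if (inherits(features, "feature_set")) features$provenance
            else list(kind = "matrix", n_features = ncol(X))
  }
  rows <- list()
  for (f in seq_len(k)) {
    te <- which(folds == f); tr <- which(folds != f)
    if (stats::sd(y[te]) == 0) {
      rows[[f]] <- tibble::tibble(fold = f, n_test = length(te), r = NA_real_)
      next
    }
    if (is.null(selector)) {
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    } else {
      fs <- selector(tr)
      Xf <- if (inherits(fs, "feature_set")) fs$matrix else fs
      Xtr <- Xf[tr, , drop = FALSE]; Xte <- Xf[te, , drop = FALSE]
    }
    pred <- fit_predict(model, Xtr, y[tr], Xte)
    rows[[f]] <- tibble::tibble(fold = f, n_test = length(te),
                                r = pearson_accuracy(y[te], pred))
  }
  per_fold <- dplyr::bind_rows(rows)
  structure(
    list(per_fold = per_fold,
         mean_r = mean(per_fold$r, na.rm = TRUE),
         sd_r = stats::sd(per_fold$r, na.rm = TRUE),
         folds = folds, model = model$name, provenance = prov, seed = seed),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d folds: mean r = %.3f (SD %.3f)\n",
              x$model, nrow(x$per_fold), x$mean_r, x$sd_r))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `cv_report`.
#' @param ... Unused.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  dplyr::mutate(x$per_fold, model = x$model)
}

#' @rdname cross_validate
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(model = x$model, k = nrow(x$per_fold),
                 mean_r = x$mean_r, sd_r = x$sd_r, seed = x$seed)
}

#' @rdname cross_validate
#' @param object A `cv_report`.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$per_fold,
                  ggplot2::aes(x = factor(.data$fold), y = .data$r)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$mean_r, linetype = 2) +
    ggplot2::labs(x = "fold", y = "Pearson r",
                  title = sprintf("%s: mean r = %.3f", object$model,
                                  object$mean_r))
}

#' Within-fold GWAS threshold selector
#'
#' Returns a selector for [cross_validate()] that reruns the kinship-corrected
#' scan on the training lines only and thresholds it — the leakage-free
#' counterpart of selecting markers on the whole panel.
#'
#' @param geno Full dosage matrix.
#' @param y Full phenotype vector.
#' @param threshold -log10(p) feature threshold.
#' @param n_pcs Genotype PCs used as fixed covariates in the scan.
#' @return `function(train_idx) -> feature_set` (columns from the training
#'   scan, rows for the full panel so folds can subset).
#' @export
threshold_selector <- function(geno, y, threshold, n_pcs = 3L) {
  force(geno); force(y); force(threshold); force(n_pcs)
  function(train_idx) {
    g <- geno[train_idx, , drop = FALSE]
    poly <- apply(g, 2, stats::sd) > 0
    g <- g[, poly, drop = FALSE]
    K <- vanraden_grm(g)
    Q <- cbind(1, genotype_pca(g)$scores[, seq_len(n_pcs), drop = FALSE])
    vc <- reml_null(y[train_idx], K, Q)
    scan <- mlm_scan(g, vc)
    ids <- scan$assoc$marker_id[scan$assoc$neg_log10_p >= threshold &
                                  !scan$assoc$collinear]
    new_feature_set(geno[, ids, drop = FALSE], kind = "threshold",
                    parameter = threshold)
  }
}

# ---- Bayesian hyperparameter optimization -----------------------------------

# Matern-5/2 kernel on scaled inputs
matern52 <- function(D, ell) {
  s <- sqrt(5) * D / ell
  (1 + s + s^2 / 3) * exp(-s)
}

gp_fit <- function(X, y, ell, noise) {
  D <- as.matrix(stats::dist(X))
  K <- matern52(D, ell) + diag(noise, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, y, transpose = TRUE))
  list(X = X, L = L, alpha = alpha, ell = ell, noise = noise,
       loglik = -sum(y * alpha) / 2 - sum(log(diag(L))) -
         nrow(X) / 2 * log(2 * pi))
}

gp_predict <- function(fit, Xnew) {
  Dx <- matrix(0, nrow(Xnew), nrow(fit$X))
  for (j in seq_len(ncol(Xnew))) {
    Dx <- Dx + outer(Xnew[, j], fit$X[, j], `-`)^2
  }
  Ks <- matern52(sqrt(Dx), fit$ell)
  mu <- drop(Ks %*% fit$alpha)
  v <- backsolve(fit$L, t(Ks), transpose = TRUE)
  s2 <- pmax(1 - colSums(v^2) + fit$noise, 1e-12)
  list(mu = mu, sd = sqrt(s2))
}

#' Gaussian-process Bayesian hyperparameter optimization
#'
#' Maximizes a (possibly noisy, expensive) objective over a box by expected
#' improvement under a Matern-5/2 Gaussian-process surrogate. The initial
#' design is a Latin hypercube of `n_init` points; each of the `n_iter`
#' iterations refits the surrogate (length-scale chosen by marginal
#' likelihood over a small grid) and evaluates the candidate with the best
#' expected improvement. Dimensions may be searched on a log scale
#' (`log_scale`) or rounded to integers (`integer`). The study budget of 20
#' initial points plus 280 iterations is the conventional full setting;
#' desk-scale runs use fewer iterations.
#'
#' @param objective `function(params) -> scalar` (larger is better); `params`
#'   is a named list. Non-finite returns are recorded as failures and the
#'   search continues.
#' @param bounds Named list of `c(lower, upper)` per hyperparameter.
#' @param n_init Initial Latin-hypercube evaluations (default 20).
#' @param n_iter Optimization iterations (default 30).
#' @param log_scale Names of dimensions searched in log space.
#' @param integer Names of dimensions rounded to integers.
#' @param n_candidates Random candidates scored per acquisition step.
#' @param seed RNG seed.
#' @return Object of class `tune_result`: `best_params`, `best_objective`,
#'   `history` tibble (params, objective), `budget`.
#' @export
bayes_opt <- function(objective, bounds, n_init = 20L, n_iter = 30L,
                      log_scale = character(), integer = character(),
                      n_candidates = 2000L, seed = 1L) {
  nm <- names(bounds)
  if (is.null(nm) || any(nm == "")) abort("`bounds` must be a named list")
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi)) {
    abort("bounds must be finite with lower < upper")
  }
  use_log <- nm %in% log_scale
  if (any(lo[use_log] <= 0)) abort("log-scale dimensions need positive bounds")
  d <- length(nm)
  # map unit-cube points to parameter space
  to_params <- function(u) {
    x <- ifelse(use_log, exp(log(lo) + u * (log(hi) - log(lo))),
                lo + u * (hi - lo))
    x[nm %in% integer] <- round(x[nm %in% integer])
    stats::setNames(as.list(pmin(hi, pmax(lo, x))), nm)
  }
  with_seed(seed, {
    U <- lhs::randomLHS(n_init, d)
    hist_u <- NULL; hist_y <- numeric(0); hist_p <- list()
    eval_point <- function(u) {
      p <- to_params(u)
      val <- tryCatch(objective(p), error = function(e) NA_real_)
      if (!is.finite(val)) val <- NA_real_
      hist_u <<- rbind(hist_u, u)
      hist_y <<- c(hist_y, val)
      hist_p[[length(hist_p) + 1]] <<- p
      val
    }
    for (i in seq_len(n_init)) eval_point(U[i, , drop = TRUE])
    for (it in seq_len(n_iter)) {
      ok <- is.finite(hist_y)
      if (sum(ok) < 2 || stats::sd(hist_y[ok]) == 0) {
        eval_point(stats::runif(d))  # flat or uninformative history
        next
      }
      ys <- scale(hist_y[ok])
      # length-scale by marginal likelihood over a coarse grid
      fits <- lapply(c(0.05, 0.1, 0.2, 0.5, 1), function(ell) {
        gp_fit(hist_u[ok, , drop = FALSE], drop(ys), ell, 1e-4)
      })
      fit <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
      cand <- matrix(stats::runif(n_candidates * d), ncol = d)
      pr <- gp_predict(fit, cand)
      best <- max(drop(ys))
      z <- (pr$mu - best) / pr$sd
      ei <- pr$sd * (z * stats::pnorm(z) + stats::dnorm(z))
      eval_point(cand[which.max(ei), , drop = TRUE])
    }
    ok <- is.finite(hist_y)
    ib <- which(ok)[which.max(hist_y[ok])]
    history <- dplyr::bind_cols(
      dplyr::bind_rows(lapply(hist_p, tibble::as_tibble)),
      tibble::tibble(objective = hist_y)
    )
    structure(
      list(best_params = hist_p[[ib]], best_objective = hist_y[ib],
           history = history, budget = c(n_init = n_init, n_iter = n_iter)),
      class = "tune_result"
    )
  })
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("<tune_result> best objective %.4f after %d evaluations\n",
              x$best_objective, nrow(x$history)))
  print(tibble::as_tibble(x$best_params))
  invisible(x)
}

#' @rdname bayes_opt
#' @param x A `tune_result`.
#' @param ... Unused.
#' @method tidy tune_result
#' @export
tidy.tune_result <- function(x, ...) x$history

#' Benchmark models across feature sets
#'
#' Runs [cross_validate()] for every model x feature-set combination — the
#' full accuracy table of a genomic-prediction comparison (models in rows,
#' GWAS-threshold / PCA / CDS feature sets in columns of the published
#' layout; emitted long here).
#'
#' @param models List of [gp_model()] specs.
#' @param feature_sets Named list of `feature_set`s (all row-aligned).
#' @param y Phenotype vector.
#' @param trait Trait label for the report.
#' @param k Folds.
#' @param seed Fold-split seed.
#' @return Tibble `trait, feature, feature_kind, n_features, model, mean_r,
#'   sd_r, seed`; empty feature sets are recorded with `NA` accuracy.
#' @export
benchmark_grid <- function(models, feature_sets, y, trait = "trait",
                           k = 10L, seed = 1L) {
  stopifnot(length(names(feature_sets)) == length(feature_sets))
  rows <- list()
  for (fn in names(feature_sets)) {
    fs <- feature_sets[[fn]]
    for (mod in models) {
      if (fs$provenance$n_features == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          trait = trait, feature = fn, feature_kind = fs$provenance$kind,
          n_features = 0L, model = mod$name, mean_r = NA_real_,
          sd_r = NA_real_, seed = seed
        )
        next
      }
      cv <- cross_validate(fs, y, mod, k = k, seed = seed)
      rows[[length(rows) + 1]] <- tibble::tibble(
        trait = trait, feature = fn, feature_kind = fs$provenance$kind,
        n_features = fs$provenance$n_features, model = mod$name,
        mean_r = cv$mean_r, sd_r = cv$sd_r, seed = seed
      )
    }
  }
  dplyr::bind_rows(rows)
}
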