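#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p * (1 - p)))` with `Z` the dosage matrix centered by
#' twice the alt-allele frequency. Row/column sums of G are zero (Z columns
#' are centered), and the trace is near `n` for a panel near Hardy-Weinberg
#' scaling.
#'
#' @param geno Dosage matrix, no missing entries.
#' @return Symmetric n x n matrix with line ids as dimnames.
#' @export
vanraden_grm <- function(geno) {
  assert_geno(geno)
  if (anyNA(geno)) abort("missing dosages: impute before computing the GRM")
  p <- alt_freq(geno)
  poly <- p > 0 & p < 1
  if (sum(poly) < 1) abort("no polymorphic markers")
  z <- sweep(geno[, poly, drop = FALSE], 2, 2 * p[poly], `-`)
  g <- tcrossprod(z) / (2 * sum(p[poly] * (1 - p[poly])))
  dimnames(g) <- list(rownames(geno), rownames(geno))
  g
}

#' Null-model REML variance components (EMMAX step 1)
#'
#' Fits `y = Q b + g + e`, `g ~ N(0, s2_g K)`, `e ~ N(0, s2_e I)` by
#' restricted maximum likelihood. A single eigendecomposition of K rotates
#' the problem so the restricted likelihood is a one-dimensional function of
#' `delta = s2_e / s2_g`, optimized by golden-section/Brent search on
#' `log(delta)` over \[1e-5, 1e5\].
#'
#' @param y Phenotype vector.
#' @param K Kinship matrix (e.g. [vanraden_grm()]).
#' @param Q Covariate matrix including an intercept column (default:
#'   intercept only).
#' @param tol Optimizer tolerance on log(delta).
#' @return List of class `emmax_null`: `sigma2_g`, `sigma2_e`, `delta`,
#'   `h2_pseudo`, `loglik`, plus the eigendecomposition reused by
#'   [mlm_scan()].
#' @export
reml_null <- function(y, K, Q = NULL, tol = 1e-6) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  Q <- Q %||% matrix(1, n, 1)
  if (!is.matrix(Q)) Q <- as.matrix(Q)
  q <- ncol(Q)
  if (qr(Q)$rank < q) abort("covariates `Q` are rank deficient")
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  if (min(eig$values) < -1e-8 * max(abs(eig$values))) {
    d <- eig$values + 1e-8 * max(abs(eig$values))  # mild PSD jitter
    if (any(d < 0)) abort("kinship matrix is not positive semidefinite")
  }
  U <- eig$vectors
  ys <- crossprod(U, y)
  Qs <- crossprod(U, Q)
  # restricted log-likelihood at a given log(delta)
  rll <- function(ld) {
    delta <- exp(ld)
    w <- 1 / (d + delta)
    sw <- sqrt(w)
    Qw <- Qs * sw
    yw <- ys * sw
    qtq <- crossprod(Qw)
    beta <- solve(qtq, crossprod(Qw, yw))
    rss <- sum((yw - Qw %*% beta)^2)
    s2 <- rss / (n - q)
    -0.5 * ((n - q) * log(2 * pi * s2) + (n - q) +
              sum(log(d + delta)) + determinant(qtq)$modulus[1] -
              determinant(crossprod(Qs))$modulus[1])
  }
  opt <- stats::optimize(rll, c(log(1e-5), log(1e5)), maximum = TRUE, tol = tol)
  delta <- exp(opt$maximum)
  w <- 1 / (d + delta)
  sw <- sqrt(w)
  Qw <- Qs * sw; yw <- ys * sw
  beta <- solve(crossprod(Qw), crossprod(Qw, yw))
  s2g <- sum((yw - Qw %*% beta)^2) / (n - q)
  structure(
    list(sigma2_g = s2g, sigma2_e = delta * s2g, delta = delta,
         h2_pseudo = 1 / (1 + delta), loglik = opt$objective,
         beta = drop(beta), U = U, d = d, Q = Q, y = y),
    class = "emmax_null"
  )
}

#' @export
print.emmax_null <- function(x, ...) {
  cat(sprintf("<emmax_null> s2_g = %.4g, s2_e = %.4g, delta = %.4g, pseudo-h2 = %.3f\n",
              x$sigma2_g, x$sigma2_e, x$delta, x$h2_pseudo))
  invisible(x)
}

#' EMMAX mixed-linear-model association scan
#'
#' With `delta` fixed from [reml_null()], every marker is tested by weighted
#' least squares on the eigen-rotated data (weights `1 / (d_i + delta)`).
#' Per-marker t statistics use `n - q - 1` degrees of freedom (q covariate
#' columns including the intercept). Markers collinear with the covariates
#' are flagged and assigned p = 1.
#'
#' @param geno Dosage matrix aligned to `y` rows.
#' @param vc A [reml_null()] fit on the same `y`, `Q`, `K`.
#' @param variants Optional variant tibble to carry chrom/pos along.
#' @return Object of class `gwas_result`: tibble `$assoc` with `marker_id`,
#'   `chrom`, `pos`, `beta`, `se`, `p`, `neg_log10_p`, `collinear`, plus
#'   scan metadata.
#' @export
mlm_scan <- function(geno, vc, variants = NULL) {
  assert_geno(geno)
  stopifnot(inherits(vc, "emmax_null"))
  n <- nrow(geno); q <- ncol(vc$Q)
  sw <- sqrt(1 / (vc$d + vc$delta))
  Xs <- crossprod(vc$U, geno) * sw        # rotated, weighted markers
  ys <- drop(crossprod(vc$U, vc$y)) * sw
  Qs <- crossprod(vc$U, vc$Q) * sw
  Px <- Xs - Qs %*% solve(crossprod(Qs), crossprod(Qs, Xs))
  py <- ys - drop(Qs %*% solve(crossprod(Qs), crossprod(Qs, ys)))
  xpx <- colSums(Px^2)
  xpy <- drop(crossprod(Px, py))
  ypy <- sum(py^2)
  df <- n - q - 1
  collinear <- xpx <= 1e-10 * max(xpx, 1)
  beta <- ifelse(collinear, 0, xpy / xpx)
  rss <- pmax(ypy - beta^2 * xpx, 0)
  se <- sqrt(rss / df / ifelse(collinear, Inf, xpx))
  tstat <- ifelse(collinear, 0, beta / se)
  p <- ifelse(collinear, 1, 2 * stats::pt(-abs(tstat), df))
  p <- pmax(p, .Machine$double.xmin)
  assoc <- tibble::tibble(
    marker_id = colnames(geno),
    chrom = if (!is.null(variants)) variants$chrom else NA_character_,
    pos = if (!is.null(variants)) variants$pos else NA_integer_,
    beta = unname(beta), se = unname(se), p = unname(p),
    neg_log10_p = unname(-log10(p)),
    collinear = unname(collinear)
  )
  structure(
    list(assoc = assoc, n = n, q = q, delta = vc$delta, df = df),
    class = "gwas_result"
  )
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("<gwas_result> %d markers, n = %d, %d covariate column(s), delta = %.3g\n",
              nrow(x$assoc), x$n, x$q, x$delta))
  top <- dplyr::arrange(x$assoc, .data$p)
  print(utils::head(top, 5))
  invisible(x)
}

#' @rdname mlm_scan
#' @param x A `gwas_result`.
#' @param ... Unused.
#' @method tidy gwas_result
#' @export
tidy.gwas_result <- function(x, ...) x$assoc

#' @rdname mlm_scan
#' @method glance gwas_result
#' @export
glance.gwas_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_markers = nrow(x$assoc), q = x$q,
                 delta = x$delta, lambda_gc = lambda_gc(x))
}

#' @rdname mlm_scan
#' @param object A `gwas_result` (Manhattan-style plot).
#' @param threshold Horizontal reference line on the -log10(p) scale.
#' @method autoplot gwas_result
#' @export
autoplot.gwas_result <- function(object, threshold = 6, ...) {
  d <- object$assoc
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$neg_log10_p,
                                  color = .data$chrom)) +
    ggplot2::geom_point(show.legend = FALSE, size = 0.6) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p)))
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`; the null median of a
#' 1-df chi-square is 0.4549364. Values near 1 indicate calibrated p-values.
#'
#' @param x A `gwas_result` or a numeric vector of p-values.
#' @return The inflation factor.
#' @export
lambda_gc <- function(x) {
  p <- if (inherits(x, "gwas_result")) x$assoc$p else x
  p <- p[is.finite(p) & p > 0 & p <= 1]
  stats::median(stats::qchisq(1 - p, df = 1)) / stats::qchisq(0.5, df = 1)
}

#' Effective number of independent markers (Li & Ji eigenvalue method)
#'
#' Per chromosome, the eigenvalues of the marker correlation matrix are
#' summarized as `sum(I(lambda >= 1) + (lambda - floor(lambda)))`; chromosome
#' contributions are added. Fully duplicated markers collapse to one
#' effective test; mutually independent markers count almost fully.
#'
#' @param geno Dosage matrix, no missing entries.
#' @param variants Optional variant tibble (enables per-chromosome blocks);
#'   without it the whole panel forms one block.
#' @return Effective marker count (float).
#' @export
effective_markers <- function(geno, variants = NULL) {
  assert_geno(geno)
  if (anyNA(geno)) abort("missing dosages: impute first")
  blocks <- if (is.null(variants)) list(seq_len(ncol(geno)))
            else split(seq_len(ncol(geno)), variants$chrom)
  me <- 0
  for (idx in blocks) {
    g <- geno[, idx, drop = FALSE]
    sds <- apply(g, 2, stats::sd)
    g <- g[, sds > 0, drop = FALSE]
    if (ncol(g) == 0) next
    ev <- eigen(stats::cor(g), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    me <- me + sum((ev >= 1) + (ev - floor(ev)))
  }
  me
}

#' Call QTL regions around significant GWAS peaks
#'
#' Markers at or above the significance threshold are grouped per chromosome
#' (markers joining a group when within `flank_bp` of its nearest member);
#' each group's peak is its smallest p (ties to the smaller coordinate) and
#' the region is the peak extended by `flank_bp` on both sides, clamped at 1.
#' The default flank matches the genome-wide LD decay distance convention.
#'
#' @param result A `gwas_result` with chrom/pos filled in.
#' @param threshold_neg_log10_p Significance threshold on -log10(p)
#'   (inclusive; default 6).
#' @param flank_bp Flank added on each side of the peak (default 52,000).
#' @return Tibble `chrom, peak_pos, peak_p, start, end, n_markers,
#'   member_markers` (1-based inclusive regions).
#' @export
call_qtl <- function(result, threshold_neg_log10_p = 6, flank_bp = 52000) {
  a <- if (inherits(result, "gwas_result")) result$assoc else result
  sig <- a[a$neg_log10_p >= threshold_neg_log10_p & !is.na(a$pos), , drop = FALSE]
  if (nrow(sig) == 0) {
    return(tibble::tibble(chrom = character(), peak_pos = integer(),
                          peak_p = numeric(), start = numeric(), end = numeric(),
                          n_markers = integer(), member_markers = list()))
  }
  out <- list()
  for (cc in unique(sig$chrom)) {
    s <- sig[sig$chrom == cc, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    grp <- cumsum(c(1, diff(s$pos) > flank_bp))
    for (g in unique(grp)) {
      sg <- s[grp == g, , drop = FALSE]
      peak <- sg[order(sg$p, sg$pos), , drop = FALSE][1, ]
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = cc,
        peak_pos = peak$pos,
        peak_p = peak$p,
        start = max(1, peak$pos - flank_bp),
        end = peak$pos + flank_bp,
        n_markers = nrow(sg),
        member_markers = list(sg$marker_id)
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' Two-class haplotype effect test at a marker
#'
#' Welch two-tailed t-test comparing phenotypes of the two homozygote classes
#' (dosage 0 vs 2; heterozygotes excluded), with the usual significance
#' stars.
#'
#' @param geno Dosage matrix.
#' @param y Phenotype vector aligned to rows of `geno`.
#' @param marker_id Marker to test.
#' @param min_group Minimum lines per homozygote class (default 5).
#' @return Tibble `marker_id, mean_ref, mean_alt, n_ref, n_alt, t, p, stars`;
#'   `t`/`p` are `NA` with a reason when a class is too small.
#' @export
haplotype_test <- function(geno, y, marker_id, min_group = 5L) {
  x <- geno[, marker_id]
  y0 <- y[!is.na(x) & x == 0]
  y2 <- y[!is.na(x) & x == 2]
  base <- tibble::tibble(
    marker_id = marker_id,
    mean_ref = mean(y0), mean_alt = mean(y2),
    n_ref = length(y0), n_alt = length(y2)
  )
  if (length(y0) < min_group || length(y2) < min_group) {
    return(dplyr::mutate(base, t = NA_real_, p = NA_real_, stars = "",
                         skipped = "homozygote class below min_group"))
  }
  if (stats::sd(y0) == 0 && stats::sd(y2) == 0 && mean(y0) == mean(y2)) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- stats::t.test(y0, y2, var.equal = FALSE)
  }
  p <- unname(tt$p.value)
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  dplyr::mutate(base, t = unname(tt$statistic), p = p, stars = stars,
                skipped = NA_character_)
}

#' Cross-trait overlap of significant markers
#'
#' For each trait the significant set is `-log10(p) > threshold` (strict by
#' convention for the suggestive threshold 3). Every non-empty trait subset
#' is reported with its plain intersection size and its exclusive
#' (upset-style) size.
#'
#' @param results Named list of `gwas_result` objects on one marker panel.
#' @param threshold_neg_log10_p Strict threshold on -log10(p) (default 3).
#' @return Tibble `traits` (plus-separated subset label), `degree`,
#'   `n_intersection`, `n_exclusive`.
#' @export
trait_overlap <- function(results, threshold_neg_log10_p = 3) {
  sets <- lapply(results, function(r) {
    a <- if (inherits(r, "gwas_result")) r$assoc else r
    a$marker_id[a$neg_log10_p > threshold_neg_log10_p]
  })
  traits <- names(sets)
  if (is.null(traits)) abort("`results` must be a named list")
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1) member <- matrix(member, nrow = 1,
                                             dimnames = list(NULL, traits))
  out <- list()
  for (k in seq_along(traits)) {
    for (combo in utils::combn(traits, k, simplify = FALSE)) {
      in_combo <- member[, combo, drop = FALSE]
      inter <- if (length(all_ids) == 0) 0L else sum(rowSums(in_combo) == k)
      excl <- if (length(all_ids) == 0) 0L else
        sum(rowSums(in_combo) == k & rowSums(member) == k)
      out[[length(out) + 1]] <- tibble::tibble(
        traits = paste(combo, collapse = "+"), degree = k,
        n_intersection = inter, n_exclusive = excl
      )
    }
  }
  dplyr::bind_rows(out)
}
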