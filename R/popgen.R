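#' Composite LD between two markers
#'
#' Squared Pearson correlation of dosage vectors over lines observed at both
#' markers (composite/dosage LD; appropriate for unphased inbred panels).
#'
#' @param geno Dosage matrix.
#' @param marker_a,marker_b Marker ids or column indices.
#' @return r-squared in \[0, 1\], or `NA` when either marker is monomorphic
#'   among the jointly observed lines.
#' @export
pairwise_r2 <- function(geno, marker_a, marker_b) {
  x <- geno[, marker_a]; y <- geno[, marker_b]
  ok <- !is.na(x) & !is.na(y)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' LD decay curve and decay distance
#'
#' Computes mean pairwise dosage r-squared for all within-chromosome marker
#' pairs separated by at most `max_dist_bp`, binned by physical distance. The
#' binned curve is smoothed by decreasing isotonic regression and the decay
#' distance is the linear interpolation of the first crossing below
#' `threshold` (the conventional r-squared = 0.2). If the curve starts below
#' the threshold, the first bin midpoint is reported; if it never crosses,
#' `Inf` is returned (decay slower than `max_dist_bp`).
#'
#' @param geno Dosage matrix (no missing entries for the fast path; pairs with
#'   missing data fall back to complete-case correlation).
#' @param variants Variant tibble aligned to `geno`.
#' @param max_dist_bp Largest pair distance considered.
#' @param bin_bp Distance bin width.
#' @param threshold r-squared threshold defining decay (default 0.2).
#' @param smooth Apply isotonic smoothing before locating the crossing.
#' @return List of class `ld_decay`: `curve` tibble
#'   (`distance_bp`, `r2`, `r2_smooth`, `n_pairs`) and
#'   `decay_distance_bp`.
#' @export
ld_decay <- function(geno, variants, max_dist_bp = 1e6, bin_bp = 2e4,
                     threshold = 0.2, smooth = TRUE) {
  assert_geno(geno)
  if (!(max_dist_bp > bin_bp && bin_bp > 0)) {
    abort("need max_dist_bp > bin_bp > 0")
  }
  dists <- numeric(0); r2s <- numeric(0)
  for (cc in unique(variants$chrom)) {
    idx <- which(variants$chrom == cc)
    idx <- idx[order(variants$pos[idx])]
    if (length(idx) < 2) next
    g <- geno[, idx, drop = FALSE]
    pos <- variants$pos[idx]
    sds <- apply(g, 2, stats::sd)
    # standardized columns -> lag-k correlations via column products
    gs <- scale(g)
    n <- nrow(g)
    for (k in seq_len(length(idx) - 1)) {
      d <- pos[(1 + k):length(pos)] - pos[1:(length(pos) - k)]
      if (all(d > max_dist_bp)) break
      i1 <- 1:(length(idx) - k); i2 <- (1 + k):length(idx)
      keep <- d <= max_dist_bp & sds[i1] > 0 & sds[i2] > 0
      if (!any(keep)) next
      r <- colSums(gs[, i1[keep], drop = FALSE] * gs[, i2[keep], drop = FALSE],
                   na.rm = TRUE) / (n - 1)
      dists <- c(dists, d[keep]); r2s <- c(r2s, r^2)
    }
  }
  if (length(dists) == 0) abort("no marker pairs within `max_dist_bp`")
  bin <- pmin(ceiling(dists / bin_bp), ceiling(max_dist_bp / bin_bp))
  curve <- tibble::tibble(bin = bin, r2 = r2s) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(r2 = mean(.data$r2), n_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$bin)
  curve$distance_bp <- (curve$bin - 0.5) * bin_bp
  # decreasing isotonic fit (isoreg fits increasing; negate)
  curve$r2_smooth <- if (smooth && nrow(curve) > 1) {
    -stats::isoreg(curve$distance_bp, -curve$r2)$yf
  } else curve$r2
  decay <- ld_crossing(curve$distance_bp, curve$r2_smooth, threshold)
  structure(
    list(curve = curve[, c("distance_bp", "r2", "r2_smooth", "n_pairs")],
         decay_distance_bp = decay, threshold = threshold),
    class = "ld_decay"
  )
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf("<ld_decay> %d bins; decay distance at r2=%.2g: %s bp\n",
              nrow(x$curve), x$threshold, format(x$decay_distance_bp)))
  invisible(x)
}

#' @rdname ld_decay
#' @param object,... Passed by the `autoplot` generic.
#' @method autoplot ld_decay
#' @export
autoplot.ld_decay <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$distance_bp)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$r2), alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$r2_smooth), color = "firebrick") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "distance (bp)", y = expression(mean~r^2))
}

# first crossing of a (smoothed, decreasing) LD curve below `threshold`,
# by linear interpolation between curve points; Inf when it never crosses,
# the first point's distance when already below there
ld_crossing <- function(d, y, threshold) {
  below <- which(y < threshold)
  if (length(below) == 0) return(Inf)
  k <- below[1]
  if (k == 1) return(d[1])
  d[k - 1] + (y[k - 1] - threshold) * (d[k] - d[k - 1]) / (y[k - 1] - y[k])
}

# Weir & Cockerham (1984) per-SNP variance components a, b, c for one marker.
# freqs: per-subpop alt frequencies; ns: per-subpop sample sizes (individuals);
# hets: per-subpop observed heterozygote proportions.
wc_components <- function(freqs, ns, hets = rep(0, length(ns))) {
  r <- length(ns)
  nbar <- mean(ns)
  nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ns * freqs) / (r * nbar)
  s2 <- sum(ns * (freqs - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ns * hets) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

#' Sliding-window Weir-Cockerham Fst
#'
#' Per-SNP Weir & Cockerham (1984) variance components are accumulated over
#' windows as a ratio of sums (`sum(a) / sum(a + b + c)`, the weighted
#' convention used by VCFtools); per-window mean of per-site ratios is
#' available via `per_site_mean = TRUE`. Windows containing no usable SNP are
#' omitted.
#'
#' @param geno Dosage matrix.
#' @param variants Variant tibble aligned to `geno`.
#' @param labels Tibble `line_id, subpop` (see [simulate_population()]).
#' @param window_bp,step_bp Window size and step (defaults 20 kb / 5 kb).
#' @param per_site_mean Average per-site Fst instead of ratio-of-sums.
#' @return Tibble `chrom, start_bp, end_bp, fst, n_snps` (1-based inclusive
#'   windows).
#' @export
windowed_fst <- function(geno, variants, labels, window_bp = 20000,
                         step_bp = 5000, per_site_mean = FALSE) {
  assert_geno(geno)
  labels <- labels[match(rownames(geno), labels$line_id), , drop = FALSE]
  if (anyNA(labels$subpop)) abort("every line must carry a subpopulation label")
  pops <- sort(unique(labels$subpop))
  if (length(pops) < 2) abort("need >= 2 subpopulations")
  comp <- matrix(NA_real_, ncol(geno), 3,
                 dimnames = list(colnames(geno), c("a", "b", "c")))
  for (j in seq_len(ncol(geno))) {
    x <- geno[, j]
    ns <- freqs <- hets <- numeric(length(pops))
    for (s in seq_along(pops)) {
      xi <- x[labels$subpop == pops[s]]
      xi <- xi[!is.na(xi)]
      ns[s] <- length(xi)
      if (length(xi) > 0) {
        freqs[s] <- mean(xi) / 2
        hets[s] <- mean(xi == 1)
      }
    }
    if (any(ns < 2)) next  # subpop effectively unobserved at this site
    comp[j, ] <- wc_components(freqs, ns, hets)
  }
  out <- list()
  for (cc in unique(variants$chrom)) {
    vi <- which(variants$chrom == cc)
    if (length(vi) == 0) next
    last <- max(variants$pos[vi])
    starts <- seq(1, max(1, last), by = step_bp)
    for (st in starts) {
      en <- st + window_bp - 1
      in_w <- vi[variants$pos[vi] >= st & variants$pos[vi] <= en]
      in_w <- in_w[!is.na(comp[in_w, 1])]
      if (length(in_w) == 0) next
      A <- comp[in_w, , drop = FALSE]
      fst <- if (per_site_mean) {
        mean(A[, 1] / rowSums(A))
      } else {
        sum(A[, 1]) / sum(A)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = cc, start_bp = st, end_bp = en,
        fst = fst, n_snps = length(in_w)
      )
    }
  }
  if (length(out) == 0) {
    warn("no window contained a usable SNP")
    return(tibble::tibble(chrom = character(), start_bp = integer(),
                          end_bp = integer(), fst = numeric(),
                          n_snps = integer()))
  }
  dplyr::bind_rows(out)
}

#' Genome-wide mean per-SNP Weir-Cockerham Fst
#'
#' Ratio-of-sums over all polymorphic SNPs (single "window" spanning the
#' panel); a scalar summary of subpopulation differentiation.
#'
#' @inheritParams windowed_fst
#' @return A single Fst value.
#' @export
mean_fst <- function(geno, variants, labels) {
  big <- windowed_fst(geno, variants, labels,
                      window_bp = max(variants$pos) + 1, step_bp = max(variants$pos) + 1)
  sum(big$fst * big$n_snps) / sum(big$n_snps)
}

#' PCA of standardized genotypes
#'
#' Markers are centered by `2 * p` and scaled by `sqrt(2 * p * (1 - p))`
#' (allele-frequency standardization); scores come from the SVD and explained
#' ratios from the squared singular values. Monomorphic markers are dropped.
#'
#' @param geno Dosage matrix with no missing entries (impute first).
#' @param n_components Number of components to keep (default: all).
#' @return Object of class `pca_result`: `scores` (lines x components),
#'   `explained` (variance ratios), `cumulative`, `n_dropped`.
#' @export
genotype_pca <- function(geno, n_components = NULL) {
  assert_geno(geno)
  if (anyNA(geno)) abort("missing dosages: impute before PCA")
  p <- alt_freq(geno)
  sc <- sqrt(2 * p * (1 - p))
  poly <- sc > 0
  z <- sweep(geno[, poly, drop = FALSE], 2, 2 * p[poly], `-`)
  z <- sweep(z, 2, sc[poly], `/`)
  sv <- svd(z)
  ev <- sv$d^2
  ratio <- ev / sum(ev)
  k <- min(n_components %||% length(ev), length(ev))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(rownames(geno), sprintf("PC%d", seq_len(k)))
  structure(
    list(scores = scores, explained = ratio[seq_len(k)],
         cumulative = cumsum(ratio)[seq_len(k)],
         n_dropped = sum(!poly)),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d lines x %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores), 100 * x$explained[1],
              100 * x$explained[min(2, length(x$explained))]))
  invisible(x)
}

#' @rdname genotype_pca
#' @param x A `pca_result`.
#' @param ... Unused.
#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$explained),
    explained = x$explained,
    cumulative = x$cumulative
  )
}

#' @rdname genotype_pca
#' @param object,labels `pca_result` and optional tibble `line_id, subpop`.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, labels = NULL, ...) {
  d <- tibble::as_tibble(object$scores[, 1:2, drop = FALSE], rownames = "line_id")
  names(d)[2:3] <- c("PC1", "PC2")
  if (!is.null(labels)) {
    d$subpop <- factor(labels$subpop[match(d$line_id, labels$line_id)])
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])
    )
  if (is.null(labels)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(color = .data$subpop))
}

#' Pairwise genetic distance (p-distance on dosages)
#'
#' `mean(|dosage_i - dosage_j|) / 2` over markers observed in both lines:
#' 0 for identical lines, 1 for lines fixed for opposite alleles everywhere.
#'
#' @param geno Dosage matrix.
#' @return Symmetric n x n matrix with zero diagonal; `NA` where a pair
#'   shares no observed marker.
#' @export
distance_matrix <- function(geno) {
  assert_geno(geno)
  if (nrow(geno) < 2) abort("need >= 2 lines")
  if (!anyNA(geno)) {
    d <- as.matrix(stats::dist(geno, method = "manhattan")) / (2 * ncol(geno))
    return(d)
  }
  n <- nrow(geno)
  d <- matrix(0, n, n, dimnames = list(rownames(geno), rownames(geno)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !is.na(geno[i, ]) & !is.na(geno[j, ])
      d[i, j] <- d[j, i] <- if (!any(shared)) NA_real_ else
        mean(abs(geno[i, shared] - geno[j, shared])) / 2
    }
  }
  d
}

#' LD pruning by pairwise r-squared
#'
#' Greedy left-to-right scan per chromosome: a marker is removed when its
#' dosage r-squared with a retained marker inside the window exceeds
#' `r2_max`. Window/step defaults follow common practice for dense panels.
#'
#' @param geno Dosage matrix.
#' @param variants Variant tibble aligned to `geno`.
#' @param r2_max Pruning threshold (default 0.2).
#' @param window_bp Window within which pairs are tested (default 500 kb).
#' @return Character vector of retained marker ids.
#' @export
ld_prune <- function(geno, variants, r2_max = 0.2, window_bp = 5e5) {
  assert_geno(geno)
  keep <- character(0)
  for (cc in unique(variants$chrom)) {
    idx <- which(variants$chrom == cc)
    idx <- idx[order(variants$pos[idx])]
    kept_pos <- numeric(0); kept_col <- integer(0)
    for (j in idx) {
      inw <- kept_col[variants$pos[j] - kept_pos <= window_bp]
      ok <- TRUE
      for (k in rev(inw)) {
        r2 <- pairwise_r2(geno, k, j)
        if (!is.na(r2) && r2 > r2_max) { ok <- FALSE; break }
      }
      if (ok) {
        kept_pos <- c(kept_pos, variants$pos[j])
        kept_col <- c(kept_col, j)
      }
    }
    keep <- c(keep, colnames(geno)[kept_col])
  }
  keep
}
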