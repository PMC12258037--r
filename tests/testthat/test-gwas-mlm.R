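test_that("VanRaden G matches its hand evaluation and algebraic identities", {
  g1 <- cbind(m1 = c(0, 2))
  rownames(g1) <- c("A", "B")
  # p = 0.5, Z = (-1, 1), denominator 2 * 0.25 = 0.5
  expect_equal(unname(vanraden_grm(g1)), rbind(c(2, -2), c(-2, 2)))
  g <- iid_geno(30, 80, seed = 61)
  g <- rbind(g, dup = g[1, ])
  K <- vanraden_grm(g)
  expect_equal(K[1, ], K[31, ], tolerance = 1e-12)
  expect_equal(max(abs(rowSums(K))), 0, tolerance = 1e-8)  # centered Z
  expect_equal(K, t(K))
  gm <- cbind(m1 = rep(0, 5), m2 = rep(2, 5))
  rownames(gm) <- sprintf("L%d", 1:5)
  expect_error(vanraden_grm(gm), "polymorphic")
})

test_that("identity kinship reduces REML to the ordinary variance partition", {
  set.seed(7)
  n <- 120
  Q <- cbind(1, rnorm(n))
  y <- drop(Q %*% c(2, 0.5)) + rnorm(n)
  K <- diag(n)
  vc <- reml_null(y, K, Q)
  ols <- lm(y ~ Q - 1)
  s2_ols <- sum(resid(ols)^2) / (n - 2)
  # with K = I only the total variance is identified
  expect_equal(vc$sigma2_g + vc$sigma2_e, s2_ols, tolerance = 1e-6)
})

test_that("REML separates genetic from residual variance on simulated panels", {
  # draw traits from the mixed model itself (s2_g = 0.8, s2_e = 0.2) on a
  # structured panel so relatedness is informative; recover pseudo-h2
  pan <- small_panel(seed = 1, n_per = c(75, 75), m_chr = 300,
                     divergence = 0.2)
  K <- vanraden_grm(pan$geno)
  ek <- eigen(K, symmetric = TRUE)
  high <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      n <- nrow(K)
      g <- drop(ek$vectors %*% (sqrt(pmax(ek$values, 0)) * rnorm(n))) *
        sqrt(0.8)
      y <- g + rnorm(n, 0, sqrt(0.2))
      reml_null(y, K)$h2_pseudo
    })
  }, numeric(1))
  expect_gte(sum(high > 0.6 & high < 0.95), 15)
  # pure-noise traits on weakly related lines stay near zero
  null <- vapply(1:20, function(s) {
    g <- iid_geno(150, 400, seed = 900 + s)
    y <- withr::with_seed(30 + s, rnorm(150))
    reml_null(y, vanraden_grm(g))$h2_pseudo
  }, numeric(1))
  expect_gte(sum(null < 0.15), 18)
})

test_that("with identity kinship the scan equals OLS association", {
  g <- iid_geno(80, 60, seed = 71)
  y <- withr::with_seed(8, rnorm(80) + 0.5 * g[, 3])
  vc <- reml_null(y, diag(80))
  scan <- mlm_scan(g, vc)
  p_ols <- vapply(seq_len(ncol(g)), function(j) {
    summary(lm(y ~ g[, j]))$coefficients[2, 4]
  }, numeric(1))
  expect_equal(scan$assoc$p, p_ols, tolerance = 1e-8)
  expect_equal(scan$assoc$neg_log10_p, -log10(scan$assoc$p), tolerance = 1e-10)
})

test_that("null markers give uniform p-values", {
  g <- iid_geno(200, 5000, seed = 72)
  y <- withr::with_seed(9, rnorm(200))
  scan <- mlm_scan(g, reml_null(y, diag(200)))
  ks <- suppressWarnings(ks.test(scan$assoc$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a QTL explaining a quarter of the variance always clears 10^-6", {
  hits <- vapply(1:20, function(s) {
    g <- iid_geno(400, 50, seed = 1100 + s)
    x <- g[, 25]
    gv <- x * sqrt(0.25 / var(x))
    y <- gv + withr::with_seed(s, rnorm(400, 0, sqrt(0.75)))
    scan <- mlm_scan(g, reml_null(y, vanraden_grm(g)))
    scan$assoc$neg_log10_p[25] > 6
  }, logical(1))
  expect_equal(sum(hits), 20)
})

test_that("markers collinear with covariates are flagged with p = 1", {
  g <- iid_geno(50, 5, seed = 73)
  Q <- cbind(1, g[, 2])
  y <- withr::with_seed(11, rnorm(50))
  scan <- mlm_scan(g, reml_null(y, diag(50), Q))
  expect_true(scan$assoc$collinear[2])
  expect_equal(scan$assoc$p[2], 1)
})

test_that("the inflation factor is calibrated", {
  p <- withr::with_seed(5, runif(1e5))
  expect_gt(lambda_gc(p), 0.97)
  expect_lt(lambda_gc(p), 1.03)
  expect_equal(lambda_gc(rep(0.5, 200)), 1)
})

test_that("effective marker counts collapse duplicated blocks", {
  g <- iid_geno(60, 1, seed = 81)
  dup <- g[, rep(1, 10)]
  colnames(dup) <- sprintf("m%d", 1:10)
  expect_equal(effective_markers(dup), 1)
  # two exactly orthogonal base markers, each duplicated five times
  g2 <- cbind(rep(c(0, 0, 2, 2), 15), rep(c(0, 2, 0, 2), 15))
  rownames(g2) <- sprintf("L%d", 1:60)
  two_blocks <- g2[, c(rep(1, 5), rep(2, 5))]
  colnames(two_blocks) <- sprintf("m%d", 1:10)
  expect_equal(effective_markers(two_blocks), 2, tolerance = 0.2)
  free <- iid_geno(500, 100, seed = 83)
  expect_gt(effective_markers(free) / 100, 0.9)
})

test_that("QTL regions reproduce the published flank arithmetic", {
  assoc <- tibble::tibble(
    marker_id = c("a", "b", "c"),
    chrom = c("A02", "C05", "C05"),
    pos = c(31103911L, 54016444L, 30000L),
    beta = 1, se = 0.1,
    p = c(6.31e-08, 1.44e-08, 1e-9),
    neg_log10_p = -log10(c(6.31e-08, 1.44e-08, 1e-9)),
    collinear = FALSE
  )
  q <- call_qtl(assoc, threshold_neg_log10_p = 6, flank_bp = 52000)
  a02 <- q[q$chrom == "A02", ]
  expect_equal(c(a02$start, a02$end), c(31051911, 31155911))
  c05 <- q[q$chrom == "C05" & q$peak_pos == 54016444, ]
  expect_equal(c(c05$start, c05$end), c(53964444, 54068444))
  # start clamps at 1 near the chromosome head
  edge <- q[q$peak_pos == 30000, ]
  expect_equal(c(edge$start, edge$end), c(1, 82000))
})

test_that("significant markers group by flank distance with min-p peaks", {
  mk <- function(pos, p) tibble::tibble(
    marker_id = sprintf("m%d", seq_along(pos)), chrom = "c1", pos = pos,
    beta = 1, se = 1, p = p, neg_log10_p = -log10(p), collinear = FALSE
  )
  # two clusters 200 kb apart; within-cluster tie broken by position
  a <- mk(c(1e6, 1e6 + 10e3, 1.3e6, 1.3e6 + 5e3),
          c(1e-7, 1e-8, 1e-9, 1e-9))
  q <- call_qtl(a, flank_bp = 52000)
  expect_equal(nrow(q), 2)
  expect_equal(q$peak_pos, c(1e6 + 10e3, 1.3e6))
  expect_true(all(q$end - q$start == 2 * 52000))
  expect_equal(nrow(call_qtl(mk(1e6, 0.5))), 0)
})

test_that("haplotype contrasts follow the Welch t-test", {
  g <- cbind(m1 = c(rep(0, 5), rep(2, 5), 1))
  rownames(g) <- sprintf("L%d", 1:11)
  y_same <- c(rep(3, 10), 9)
  r0 <- haplotype_test(g, y_same, "m1")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$stars, "")
  y <- c(1, 2, 3, 1.5, 2.5, 4, 5, 6, 4.5, 5.5, 0)
  r <- haplotype_test(g, y, "m1")
  oracle <- t.test(y[1:5], y[6:10])
  expect_equal(r$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(r$p, oracle$p.value, tolerance = 1e-12)
  # heterozygote excluded from both groups
  expect_equal(r$n_ref + r$n_alt, 10)
  small <- haplotype_test(g[1:7, , drop = FALSE], y[1:7], "m1")
  expect_true(is.na(small$p))
})

test_that("a planted major locus earns three stars", {
  stars <- vapply(1:20, function(s) {
    g <- iid_geno(120, 40, seed = 1300 + s)
    x <- g[, 7]
    y <- x * 2 + withr::with_seed(60 + s, rnorm(120))
    haplotype_test(g, y, colnames(g)[7])$stars
  }, character(1))
  expect_equal(sum(stars == "***"), 20)
})

test_that("trait overlap counts exact subset intersections", {
  mk <- function(ids, m = 10) {
    nl <- -log10(seq(0.5, 0.9, length.out = m))
    a <- tibble::tibble(marker_id = sprintf("m%d", 1:m), chrom = "c1",
                        pos = 1:m, beta = 0, se = 1, p = 10^-nl,
                        neg_log10_p = nl, collinear = FALSE)
    a$neg_log10_p[a$marker_id %in% ids] <- 5
    a$p[a$marker_id %in% ids] <- 1e-5
    a
  }
  ov <- trait_overlap(list(t1 = mk(c("m1", "m2")), t2 = mk("m3")),
                      threshold_neg_log10_p = 3)
  expect_equal(ov$n_intersection[ov$traits == "t1+t2"], 0)
  ov2 <- trait_overlap(list(t1 = mk(c("m1", "m2", "m3")),
                            t2 = mk(c("m2", "m3"))))
  expect_equal(ov2$n_intersection[ov2$traits == "t1+t2"], 2)
  expect_equal(ov2$n_exclusive[ov2$traits == "t1"], 1)
  ov3 <- trait_overlap(list(a = mk("m1"), b = mk("m1"), c = mk("m1")))
  expect_equal(ov3$n_intersection[ov3$traits == "a+b+c"], 1)
})

test_that("pleiotropic loci surface in the triple overlap", {
  hits <- vapply(1:20, function(s) {
    g <- iid_geno(250, 300, seed = 1500 + s)
    x <- g[, 150]
    res <- lapply(1:3, function(tr) {
      y <- x * 1 + withr::with_seed(100 * tr + s, rnorm(250))
      mlm_scan(g, reml_null(y, vanraden_grm(g)))
    })
    names(res) <- c("t1", "t2", "t3")
    ov <- trait_overlap(res, threshold_neg_log10_p = 3)
    ov$n_intersection[ov$traits == "t1+t2+t3"] >= 1
  }, logical(1))
  expect_gte(sum(hits), 18)
})
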