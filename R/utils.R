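#' @importFrom Rcpp evalCpp
#' @importFrom rlang %||% abort warn .data
#' @useDynLib gwaspred, .registration = TRUE
#' @keywords internal
"_PACKAGE"

# run `expr` under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# derive a reproducible child seed for stage `k` of a pipeline rooted at `seed`;
# kept below 2^31 so it is always a valid R integer
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647L)
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || any(x <= 0) || any(x != floor(x))) {
    abort(sprintf("`%s` must be a positive integer", name))
  }
  invisible(x)
}

# dosage matrix sanity: numeric lines x markers with dimnames
assert_geno <- function(geno) {
  if (!is.matrix(geno) || !is.numeric(geno)) {
    abort("`geno` must be a numeric lines x markers matrix")
  }
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    abort("`geno` must carry line ids (rownames) and marker ids (colnames)")
  }
  invisible(geno)
}

# alt-allele frequency per marker from non-missing calls
alt_freq <- function(geno) colMeans(geno, na.rm = TRUE) / 2

# minor allele frequency per marker
maf_of <- function(geno) {
  p <- alt_freq(geno)
  pmin(p, 1 - p)
}

pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}
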