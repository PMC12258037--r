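#' Marker features passing a GWAS significance threshold
#'
#' Extracts the dosage columns of markers with `-log10(p) >= threshold`
#' (inclusive by default, so a "3P" set contains markers at exactly 3.0;
#' `strict = TRUE` for strictly above). Feature sets are nested: every
#' marker in the 5P set is in the 3P set of the same scan.
#'
#' @param geno Dosage matrix.
#' @param result `gwas_result` aligned to `geno` columns.
#' @param threshold -log10(p) threshold (3, 3.5, 4, 4.5, 5 in the usual
#'   ladder).
#' @param strict Use a strict inequality.
#' @param trait Optional trait label recorded in the provenance.
#' @return Object of class `feature_set`: `matrix` (lines x features),
#'   `feature_ids`, `provenance` list (kind/parameter/n_features/trait).
#' @export
threshold_features <- function(geno, result, threshold, strict = FALSE,
                               trait = NULL) {
  assert_geno(geno)
  a <- if (inherits(result, "gwas_result")) result$assoc else result
  if (!all(a$marker_id %in% colnames(geno))) {
    abort("GWAS result is not aligned to the genotype matrix")
  }
  pass <- if (strict) a$neg_log10_p > threshold else a$neg_log10_p >= threshold
  ids <- a$marker_id[pass & !a$collinear]
  if (length(ids) == 0) warn(sprintf("no markers pass -log10(p) %s %s",
                                     if (strict) ">" else ">=", threshold))
  new_feature_set(geno[, ids, drop = FALSE], kind = "threshold",
                  parameter = threshold, trait = trait)
}

#' Principal-component score features
#'
#' Standardized-genotype PCA scores for the smallest number of components
#' whose cumulative explained variance reaches `cumulative_target`.
#'
#' @param geno Imputed dosage matrix.
#' @param cumulative_target Cumulative explained-variance target in (0, 1\]
#'   (default 0.95).
#' @return A `feature_set` of PC scores.
#' @export
pca_features <- function(geno, cumulative_target = 0.95) {
  if (cumulative_target > 1 || cumulative_target <= 0) {
    abort("`cumulative_target` must lie in (0, 1]")
  }
  pca <- genotype_pca(geno)
  k <- which(pca$cumulative >= cumulative_target - 1e-12)[1]
  if (is.na(k)) k <- length(pca$cumulative)
  new_feature_set(pca$scores[, seq_len(k), drop = FALSE], kind = "pca",
                  parameter = cumulative_target)
}

#' Systematically subsampled CDS SNP features
#'
#' Restricts to CDS SNPs (`is_cds` and not `is_indel`), orders them by
#' (chromosome, position) and keeps every `step`-th variant starting from a
#' seeded random offset — systematic 1-in-`step` sampling. `bernoulli = TRUE`
#' instead keeps each CDS SNP independently with probability `1/step`.
#'
#' @param geno Dosage matrix.
#' @param variants Variant tibble with `is_cds`/`is_indel` flags.
#' @param step Sampling stride (default 20).
#' @param seed RNG seed for the offset.
#' @param bernoulli Use independent 1/step sampling instead of a stride.
#' @return A `feature_set` of dosage columns.
#' @export
cds_features <- function(geno, variants, step = 20L, seed = 1L,
                         bernoulli = FALSE) {
  assert_geno(geno)
  assert_count(step, "step")
  cds <- variants[variants$is_cds & !variants$is_indel, , drop = FALSE]
  cds <- cds[order(cds$chrom, cds$pos), , drop = FALSE]
  if (nrow(cds) == 0) {
    warn("no CDS SNPs available")
    return(new_feature_set(geno[, 0, drop = FALSE], kind = "cds",
                           parameter = step))
  }
  ids <- with_seed(seed, {
    if (bernoulli) {
      cds$marker_id[stats::runif(nrow(cds)) < 1 / step]
    } else {
      offset <- sample.int(step, 1) - 1L  # offset in [0, step)
      take <- seq(1 + offset, nrow(cds), by = step)
      if (length(take) == 0) take <- 1L  # tiny panels keep at least one SNP
      cds$marker_id[take]
    }
  })
  new_feature_set(geno[, ids, drop = FALSE], kind = "cds", parameter = step)
}

new_feature_set <- function(m, kind, parameter, trait = NULL) {
  structure(
    list(
      matrix = m,
      feature_ids = colnames(m),
      provenance = list(kind = kind, parameter = parameter,
                        n_features = ncol(m), trait = trait)
    ),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s (parameter %s): %d lines x %d features\n",
              x$provenance$kind, format(x$provenance$parameter),
              nrow(x$matrix), x$provenance$n_features))
  invisible(x)
}

#' Save / load a feature set as 012-style TSV plus JSON provenance
#'
#' @param x A `feature_set`.
#' @param path Output TSV path (a `.json` sidecar is written next to it).
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(x, path) {
  stopifnot(inherits(x, "feature_set"))
  df <- tibble::as_tibble(x$matrix, rownames = "line_id")
  readr::write_tsv(df, path, progress = FALSE)
  jsonlite::write_json(x$provenance, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
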