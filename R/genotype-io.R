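#' Read a VCF into a dosage matrix and variant table
#'
#' Parses GT fields of a VCF (v4.x) via the vcfR reader and converts calls to
#' alt-allele dosages: `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`,
#' `./. -> NA`. Phase separators (`|`) are accepted. Multiallelic records are
#' rejected by default because the downstream pipeline is biallelic.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param region Optional `"chrom:start-end"` restriction (1-based inclusive).
#' @param multiallelic `"error"` (default) or `"drop"`.
#' @return List with `geno` (lines x markers dosage matrix) and `variants`
#'   tibble (`marker_id`, `chrom`, `pos`, `ref`, `alt`, `maf`, `missing_rate`,
#'   `is_cds`, `is_indel`).
#' @export
read_vcf <- function(path, region = NULL, multiallelic = c("error", "drop")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  fix$POS <- as.integer(fix$POS)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    if (multiallelic == "error") {
      abort(sprintf("%d multiallelic record(s); biallelic input required", sum(multi)))
    }
    warn(sprintf("dropping %d multiallelic record(s)", sum(multi)))
  }
  keep <- !multi
  if (!is.null(region)) {
    parts <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(parts) != 4) abort("`region` must look like 'chrom:start-end'")
    keep <- keep & fix$CHROM == parts[2] &
      fix$POS >= as.integer(parts[3]) & fix$POS <= as.integer(parts[4])
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  allele_sum <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    vapply(a, function(g) {
      if (any(g == "." | is.na(g))) return(NA_real_)
      sum(as.numeric(g))
    }, numeric(1))
  }
  dos <- apply(gt, 2, function(col) allele_sum(col))
  dos[is.na(gt)] <- NA
  geno <- t(matrix(dos, nrow = nrow(fix),
                   dimnames = list(NULL, colnames(gt))))
  marker_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                      sprintf("%s_%d", fix$CHROM, fix$POS), fix$ID)
  colnames(geno) <- marker_id
  variants <- tibble::tibble(
    marker_id = marker_id,
    chrom = fix$CHROM,
    pos = fix$POS,
    ref = fix$REF,
    alt = fix$ALT,
    maf = unname(maf_of(geno)),
    missing_rate = unname(colMeans(is.na(geno))),
    is_cds = FALSE,
    is_indel = nchar(fix$REF) != nchar(fix$ALT)
  )
  list(geno = geno, variants = variants)
}

#' Write a dosage panel as VCF v4.2
#'
#' Serializes homozygous-coded dosages back to GT-only VCF records
#' (`0 -> 0/0`, `1 -> 0/1`, `2 -> 1/1`, `NA -> ./.`).
#'
#' @param geno Dosage matrix (lines x markers).
#' @param variants Variant tibble aligned to `geno` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, variants, path) {
  assert_geno(geno)
  stopifnot(nrow(variants) == ncol(geno))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(nrow(variants)), function(j) {
    calls <- gt_code[as.character(geno[, j])]
    calls[is.na(calls)] <- "./."
    paste(c(variants$chrom[j], variants$pos[j], variants$marker_id[j],
            variants$ref[j], variants$alt[j], ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gwaspred",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Filter variants on minor-allele frequency and missingness
#'
#' Keeps markers with `maf > maf_min` and `missing_rate < missing_max`
#' (strict inequalities by default; MAF computed from non-missing calls).
#'
#' @param geno Dosage matrix.
#' @param variants Variant tibble aligned to `geno`.
#' @param maf_min MAF threshold (default 0.05).
#' @param missing_max Missing-rate threshold (default 0.10).
#' @param strict Use strict inequalities (default); `FALSE` for inclusive.
#' @return List `geno`, `variants` restricted to retained markers, with the
#'   `maf` / `missing_rate` columns refreshed.
#' @export
filter_variants <- function(geno, variants, maf_min = 0.05, missing_max = 0.10,
                            strict = TRUE) {
  assert_geno(geno)
  stopifnot(nrow(variants) == ncol(geno))
  if (maf_min < 0 || maf_min > 0.5) abort("`maf_min` must lie in [0, 0.5]")
  if (missing_max < 0 || missing_max > 1) abort("`missing_max` must lie in [0, 1]")
  maf <- maf_of(geno)
  mis <- colMeans(is.na(geno))
  keep <- if (strict) maf > maf_min & mis < missing_max
          else maf >= maf_min & mis <= missing_max
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warn("all markers removed by the MAF/missingness filter")
  geno <- geno[, keep, drop = FALSE]
  variants <- variants[keep, , drop = FALSE]
  variants$maf <- unname(maf[keep])
  variants$missing_rate <- unname(mis[keep])
  list(geno = geno, variants = variants)
}

#' Impute missing dosages
#'
#' @param geno Dosage matrix with `NA` for missing calls.
#' @param method `"mode"` (most frequent dosage, ties to the lower dosage;
#'   default), `"mean"` (column mean), or `"knn"` (average over the `k`
#'   nearest lines by Hamming distance on jointly observed markers).
#' @param round_mean Round mean imputations to the nearest of 0/1/2 (default);
#'   `FALSE` keeps fractional dosages for dosage-based models.
#' @param k Neighbours for `"knn"`.
#' @return The matrix with no missing entries; observed entries untouched.
#' @export
impute_missing <- function(geno, method = c("mode", "mean", "knn"),
                           round_mean = TRUE, k = 5L) {
  method <- match.arg(method)
  assert_geno(geno)
  all_missing <- colSums(!is.na(geno)) == 0
  if (any(all_missing)) {
    abort(sprintf("marker(s) with no observed calls: %s",
                  paste(utils::head(colnames(geno)[all_missing], 3), collapse = ", ")))
  }
  if (!anyNA(geno)) return(geno)
  if (method == "mode") {
    for (j in which(colSums(is.na(geno)) > 0)) {
      x <- geno[, j]
      tab <- table(x[!is.na(x)])
      # ties break toward the lower dosage (names are sorted ascending)
      fill <- as.numeric(names(tab)[which.max(tab)])
      geno[is.na(x), j] <- fill
    }
  } else if (method == "mean") {
    mu <- colMeans(geno, na.rm = TRUE)
    if (round_mean) mu <- pmin(2, pmax(0, round(mu)))
    idx <- which(is.na(geno), arr.ind = TRUE)
    geno[idx] <- mu[idx[, 2]]
  } else {
    filled <- geno
    for (i in which(rowSums(is.na(geno)) > 0)) {
      obs_i <- !is.na(geno[i, ])
      d <- vapply(seq_len(nrow(geno)), function(l) {
        shared <- obs_i & !is.na(geno[l, ])
        if (l == i || !any(shared)) return(Inf)
        mean(geno[i, shared] != geno[l, shared])
      }, numeric(1))
      nn <- order(d)[seq_len(min(k, sum(is.finite(d))))]
      for (j in which(is.na(geno[i, ]))) {
        vals <- geno[nn, j]
        vals <- vals[!is.na(vals)]
        filled[i, j] <- if (length(vals) > 0) mean(vals) else
          mean(geno[, j], na.rm = TRUE)
      }
    }
    geno <- filled
  }
  geno
}

#' Read BED intervals
#'
#' Plain three-column BED (chrom, start, end), 0-based half-open.
#'
#' @param path BED file path.
#' @return Tibble `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                  col_types = "cii", progress = FALSE)
}

#' Flag variants inside CDS intervals
#'
#' Intervals follow the BED convention (0-based half-open), variant positions
#' are 1-based: position `p` is inside `(start, end]` after conversion.
#'
#' @param variants Variant tibble.
#' @param intervals Tibble `chrom`, `start`, `end` (see [read_bed()]).
#' @return `variants` with `is_cds` set.
#' @export
annotate_cds <- function(variants, intervals) {
  unknown <- setdiff(unique(intervals$chrom), unique(variants$chrom))
  if (length(unknown) > 0) {
    warn(sprintf("skipping interval(s) on unknown chromosome(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  variants$is_cds <- FALSE
  for (cc in intersect(unique(intervals$chrom), unique(variants$chrom))) {
    iv <- intervals[intervals$chrom == cc, , drop = FALSE]
    # merge overlapping/adjacent intervals so a sorted scan suffices
    iv <- iv[order(iv$start), , drop = FALSE]
    ms <- me <- numeric(0)
    for (r in seq_len(nrow(iv))) {
      if (length(ms) > 0 && iv$start[r] <= me[length(me)]) {
        me[length(me)] <- max(me[length(me)], iv$end[r])
      } else {
        ms <- c(ms, iv$start[r]); me <- c(me, iv$end[r])
      }
    }
    vi <- which(variants$chrom == cc)
    p <- variants$pos[vi]
    hit <- findInterval(p - 1L, ms)  # interval whose start is <= p-1
    inside <- hit > 0 & p <= me[pmax(hit, 1)]
    variants$is_cds[vi] <- inside
  }
  variants
}

#' Write a 012 dosage matrix
#'
#' Tab-separated: header `line_id` + marker ids, one row per line.
#'
#' @param geno Dosage matrix (missing entries written as `NA`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_012 <- function(geno, path) {
  assert_geno(geno)
  df <- tibble::as_tibble(geno, rownames = "line_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a 012 dosage matrix written by [write_dosage_012()]
#'
#' @param path File path.
#' @return Dosage matrix with line ids as rownames.
#' @export
read_dosage_012 <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    line_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$line_id
  m
}
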