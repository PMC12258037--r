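#' Per-line BLUP breeding values from replicated multi-year records
#'
#' Fits, per trait, the mixed model `value ~ year + (1 | line)` by REML
#' (year fixed, replicate absorbed into the residual; set
#' `year_random = TRUE` for `(1 | year)` instead) and extracts each line's
#' BLUP as the average fixed-effect prediction plus its shrunken random
#' effect. For a balanced design this equals the classic shrinkage form
#' `mu + (s2_line / (s2_line + s2_e / r)) * (ybar_i - mu)` with `r`
#' observations per line.
#'
#' @param records Long tibble `line_id, year, rep, trait, value`.
#' @param traits Traits to fit (default: all present).
#' @param year_random Model year as a random instead of fixed effect.
#' @return Object of class `blup_fit`: `$blups` (tibble `line_id, trait,
#'   blup`), `$vc` (tibble of REML variance components per trait).
#' @export
fit_blup <- function(records, traits = NULL, year_random = FALSE) {
  need <- c("line_id", "year", "trait", "value")
  if (!all(need %in% names(records))) {
    abort("`records` needs columns line_id, year, rep, trait, value")
  }
  if (anyDuplicated(records[, intersect(c("line_id", "year", "rep", "trait"),
                                        names(records))])) {
    abort("duplicate (line, year, rep, trait) records")
  }
  traits <- traits %||% unique(records$trait)
  out_b <- list(); out_v <- list()
  for (tr in traits) {
    d <- records[records$trait == tr & is.finite(records$value), , drop = FALSE]
    if (length(unique(d$line_id)) < 2) abort("need >= 2 lines per trait")
    d$line_id <- factor(d$line_id)
    d$year <- factor(d$year)
    form <- if (year_random) value ~ 1 + (1 | year) + (1 | line_id)
            else if (nlevels(d$year) > 1) value ~ year + (1 | line_id)
            else value ~ 1 + (1 | line_id)
    fit <- lme4::lmer(form, data = d, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2 <- function(g) {
      v <- vc$vcov[vc$grp == g]
      if (length(v) == 0) NA_real_ else v
    }
    u <- lme4::ranef(fit)$line_id[, 1]
    names(u) <- rownames(lme4::ranef(fit)$line_id)
    # average fixed-effect prediction over the observed design = mu-hat
    mu_hat <- mean(stats::predict(fit, re.form = NA))
    out_b[[tr]] <- tibble::tibble(
      line_id = levels(d$line_id),
      trait = tr,
      blup = unname(mu_hat + u[levels(d$line_id)])
    )
    out_v[[tr]] <- tibble::tibble(
      trait = tr,
      sigma2_line = s2("line_id"),
      sigma2_year = s2("year"),
      sigma2_residual = s2("Residual")
    )
  }
  structure(
    list(blups = dplyr::bind_rows(out_b), vc = dplyr::bind_rows(out_v)),
    class = "blup_fit"
  )
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("<blup_fit> %d lines x %d trait(s)\n",
              length(unique(x$blups$line_id)), nrow(x$vc)))
  print(x$vc)
  invisible(x)
}

#' @rdname fit_blup
#' @param x A `blup_fit`.
#' @param ... Unused.
#' @method tidy blup_fit
#' @export
tidy.blup_fit <- function(x, ...) x$blups

#' @rdname fit_blup
#' @method glance blup_fit
#' @export
glance.blup_fit <- function(x, ...) {
  dplyr::mutate(
    x$vc,
    repeatability = .data$sigma2_line /
      (.data$sigma2_line + .data$sigma2_residual)
  )
}

#' Wide line x trait matrix of BLUPs
#'
#' @param x A `blup_fit` or a long tibble `line_id, trait, blup`.
#' @return Tibble with `line_id` and one column per trait.
#' @export
blup_wide <- function(x) {
  b <- if (inherits(x, "blup_fit")) x$blups else x
  tidyr::pivot_wider(b, id_cols = "line_id", names_from = "trait",
                     values_from = "blup")
}

#' Descriptive statistics of trait BLUPs
#'
#' Max, min, mean, sample variance (n - 1 denominator) and SD per trait.
#'
#' @param x A `blup_fit` or long tibble `line_id, trait, blup`.
#' @return Tibble, one row per trait.
#' @export
summarize_traits <- function(x) {
  b <- if (inherits(x, "blup_fit")) x$blups else x
  if (nrow(b) == 0) abort("no BLUPs to summarize")
  dplyr::summarise(
    dplyr::group_by(b, .data$trait),
    max = max(.data$blup), min = min(.data$blup), mean = mean(.data$blup),
    variance = stats::var(.data$blup), sd = stats::sd(.data$blup),
    .groups = "drop"
  )
}

#' Pairwise Pearson correlations among trait BLUPs
#'
#' Two-tailed p-values from `t = r * sqrt((n - 2) / (1 - r^2))`. Zero-variance
#' traits yield `NA` correlations.
#'
#' @param x A `blup_fit` or long tibble `line_id, trait, blup`.
#' @return Tibble `trait_a, trait_b, n, r, p` covering all unordered pairs
#'   (including the diagonal with r = 1).
#' @export
correlate_traits <- function(x) {
  w <- blup_wide(x)
  traits <- setdiff(names(w), "line_id")
  pairs <- tidyr::expand_grid(trait_a = traits, trait_b = traits)
  pairs <- pairs[match(pairs$trait_a, traits) <= match(pairs$trait_b, traits), ]
  res <- purrr::pmap_dfr(pairs, function(trait_a, trait_b) {
    xv <- w[[trait_a]]; yv <- w[[trait_b]]
    ok <- is.finite(xv) & is.finite(yv)
    n <- sum(ok)
    if (n < 3 || stats::sd(xv[ok]) == 0 || stats::sd(yv[ok]) == 0) {
      return(tibble::tibble(trait_a, trait_b, n, r = NA_real_, p = NA_real_))
    }
    r <- stats::cor(xv[ok], yv[ok])
    p <- if (abs(r) >= 1) 0 else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tstat), n - 2)
    }
    tibble::tibble(trait_a, trait_b, n, r, p)
  })
  res
}
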