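#' Configuration for the breeding-panel simulator
#'
#' Describes a structured panel of inbred lines: subpopulation sizes, marker
#' map, founder haplotype pools, recombination and allele-frequency divergence.
#' Defaults emulate a worldwide rapeseed diversity panel of 404 lines split
#' into three vernalization ecotypes (165 semiwinter / 61 spring / 178 winter),
#' scaled down in marker count so a panel simulates in seconds.
#'
#' @param n_lines_per_subpop Integer vector, lines per subpopulation.
#' @param n_chromosomes Number of chromosomes.
#' @param markers_per_chromosome Markers simulated per chromosome.
#' @param chromosome_length_bp Physical length of each chromosome (bp).
#' @param n_founder_haplotypes Founder haplotypes per subpopulation; each line
#'   is a recombinant mosaic of two founders from its own pool, doubled. A
#'   small pool emulates the high local haplotype redundancy (baseline
#'   adjacent-marker r-squared of roughly `1 / (pool - 1)`) seen in breeding
#'   panels.
#' @param recombination_rate Expected crossovers per chromosome per meiosis
#'   (Poisson mean; >= 0). Controls LD decay: more crossovers, faster decay.
#' @param n_generations Breeding generations over which crossovers
#'   accumulate; the realized crossover count per chromosome is
#'   Poisson(`recombination_rate * n_generations`), so historical
#'   recombination — not a single meiosis — sets the LD decay scale.
#' @param subpop_divergence Balding-Nichols drift parameter F in \[0, 1\]:
#'   subpopulation allele frequencies are Beta-distributed around an ancestral
#'   frequency with E\[Fst\] approximately F.
#' @param maf_floor Minimum panel minor-allele frequency; markers below it are
#'   redrawn (then dropped if persistently rare). Set 0 to disable.
#' @param residual_het Per-entry probability of a residual heterozygous call
#'   (dosage 1) in otherwise fully inbred lines.
#' @param seed Root RNG seed; every simulator stage derives a child seed from
#'   it, so all outputs are pure functions of (config, seed).
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_lines_per_subpop = c(165L, 61L, 178L),
                       n_chromosomes = 2L,
                       markers_per_chromosome = 500L,
                       chromosome_length_bp = 20e6,
                       n_founder_haplotypes = 5L,
                       recombination_rate = 2,
                       n_generations = 10L,
                       subpop_divergence = 0.15,
                       maf_floor = 0.05,
                       residual_het = 0,
                       seed = 1L) {
  assert_count(n_lines_per_subpop, "n_lines_per_subpop")
  assert_count(n_chromosomes, "n_chromosomes")
  assert_count(markers_per_chromosome, "markers_per_chromosome")
  assert_count(chromosome_length_bp, "chromosome_length_bp")
  assert_count(n_founder_haplotypes, "n_founder_haplotypes")
  if (recombination_rate < 0) abort("`recombination_rate` must be >= 0")
  assert_count(n_generations, "n_generations")
  if (subpop_divergence < 0 || subpop_divergence > 1) {
    abort("`subpop_divergence` must lie in [0, 1]")
  }
  if (maf_floor < 0 || maf_floor >= 0.5) abort("`maf_floor` must lie in [0, 0.5)")
  if (residual_het < 0 || residual_het >= 1) abort("`residual_het` must lie in [0, 1)")
  if (markers_per_chromosome > chromosome_length_bp) {
    abort("more markers than base pairs on a chromosome")
  }
  structure(
    list(
      n_lines_per_subpop = as.integer(n_lines_per_subpop),
      n_chromosomes = as.integer(n_chromosomes),
      markers_per_chromosome = as.integer(markers_per_chromosome),
      chromosome_length_bp = as.numeric(chromosome_length_bp),
      n_founder_haplotypes = as.integer(n_founder_haplotypes),
      recombination_rate = recombination_rate,
      n_generations = as.integer(n_generations),
      subpop_divergence = subpop_divergence,
      maf_floor = maf_floor,
      residual_het = residual_het,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# subpopulation allele frequencies under the Balding-Nichols model
bn_subpop_freq <- function(p0, f) {
  if (f <= 0) return(p0)
  if (f >= 1) return(as.numeric(stats::rbinom(length(p0), 1, p0)))
  stats::rbeta(length(p0), p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
}

#' Simulate a structured panel of inbred lines
#'
#' Founder haplotype pools are drawn per subpopulation under the
#' Balding-Nichols divergence model; each line is a recombinant mosaic of two
#' founder haplotypes from its own pool (crossover count ~ Poisson, positions
#' uniform along the chromosome), doubled to homozygosity. Dosages are
#' therefore in \{0, 2\} unless `residual_het > 0`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_panel` with elements `geno` (lines x markers
#'   dosage matrix), `variants` (tibble of marker metadata), and `subpops`
#'   (tibble `line_id`, `subpop` with 0-based contiguous labels).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_sub <- length(config$n_lines_per_subpop)
    n_lines <- sum(config$n_lines_per_subpop)
    m_chr <- config$markers_per_chromosome
    m <- config$n_chromosomes * m_chr
    nf <- config$n_founder_haplotypes

    # stage 1: marker map (strictly increasing positions per chromosome)
    chrom <- rep(sprintf("chr%02d", seq_len(config$n_chromosomes)), each = m_chr)
    pos <- unlist(lapply(seq_len(config$n_chromosomes), function(.c) {
      sort(sample.int(config$chromosome_length_bp, m_chr))
    }))

    # stage 2: line -> (founder pair, crossover mosaic), independent of alleles
    subpop <- rep(seq_len(n_sub) - 1L, config$n_lines_per_subpop)
    origin <- matrix(0L, n_lines, m)  # global founder row index per locus
    for (i in seq_len(n_lines)) {
      pool0 <- subpop[i] * nf  # offset of this subpop's founder rows
      pair <- pool0 + sample.int(nf, 2, replace = TRUE)
      for (cc in seq_len(config$n_chromosomes)) {
        idx <- ((cc - 1) * m_chr + 1):(cc * m_chr)
        ncross <- stats::rpois(1, config$recombination_rate *
                                 config$n_generations)
        seg <- rep(1L, m_chr)
        if (ncross > 0) {
          cuts <- sort(stats::runif(ncross, 0, config$chromosome_length_bp))
          seg <- 1L + (findInterval(pos[idx], cuts) %% 2L)
        }
        origin[i, idx] <- pair[seg]
      }
    }

    # stage 3: ancestral and subpopulation frequencies, founder alleles;
    # markers under the MAF floor are redrawn (mosaic unchanged), then dropped
    draw_alleles <- function(mm) {
      p0 <- stats::runif(mm, 0.05, 0.95)
      h <- matrix(0L, n_sub * nf, mm)
      for (s in seq_len(n_sub)) {
        ps <- bn_subpop_freq(p0, config$subpop_divergence)
        rows <- ((s - 1) * nf + 1):(s * nf)
        h[rows, ] <- stats::rbinom(nf * mm, 1, rep(ps, each = nf))
      }
      h
    }
    founders <- draw_alleles(m)
    dose_of <- function(cols) {
      hap <- matrix(founders[cbind(as.vector(origin[, cols, drop = FALSE]),
                                   rep(cols, each = n_lines))],
                    n_lines, length(cols))
      2 * hap
    }
    geno <- dose_of(seq_len(m))
    if (config$maf_floor > 0) {
      for (round in 1:25) {
        bad <- which(maf_of(geno) < config$maf_floor)
        if (length(bad) == 0) break
        founders[, bad] <- draw_alleles(length(bad))
        geno[, bad] <- dose_of(bad)
      }
      keep <- maf_of(geno) >= config$maf_floor
    } else {
      keep <- rep(TRUE, m)
    }

    # stage 4: optional residual heterozygosity
    if (config$residual_het > 0) {
      flip <- stats::runif(length(geno)) < config$residual_het
      geno[flip] <- 1
    }

    line_id <- sprintf("L%04d", seq_len(n_lines))
    marker_id <- sprintf("%s_%d", chrom, pos)
    dimnames(geno) <- list(line_id, marker_id)
    geno <- geno[, keep, drop = FALSE]

    variants <- tibble::tibble(
      marker_id = marker_id[keep],
      chrom = chrom[keep],
      pos = as.integer(pos[keep]),
      ref = "A",
      alt = "T",
      maf = unname(maf_of(geno)),
      missing_rate = unname(colMeans(is.na(geno))),
      is_cds = FALSE,
      is_indel = FALSE
    )
    structure(
      list(
        geno = geno,
        variants = variants,
        subpops = tibble::tibble(line_id = line_id, subpop = subpop)
      ),
      class = "sim_panel"
    )
  })
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf(
    "<sim_panel> %d lines x %d markers, %d subpopulations (%s)\n",
    nrow(x$geno), ncol(x$geno), length(unique(x$subpops$subpop)),
    paste(table(x$subpops$subpop), collapse = "/")
  ))
  invisible(x)
}

#' Plant additive QTL on a simulated panel
#'
#' Samples causal markers without replacement and assigns additive allele
#' effects. Large-effect QTL are rescaled so that, jointly, they contribute
#' `large_var_share` of the genetic variance realized in this sample (small
#' QTL carry the remainder); variances are computed directly from the dosage
#' columns, so the calibration is exact for the panel at hand.
#'
#' @param geno Dosage matrix (lines x markers).
#' @param variants Variant tibble aligned to `geno` columns.
#' @param n_large,n_small Number of large- and small-effect QTL.
#' @param large_var_share Share of genetic variance carried by the large QTL
#'   (in (0, 1); ignored when one of the groups is empty).
#' @param h2 Narrow-sense heritability of line means targeted by
#'   [simulate_phenotypes()], in (0, 1\].
#' @param year_effect_sd SD of the common year effect (trait units).
#' @param trait_name Trait label carried through to phenotype records.
#' @param major_locus_id Optional marker id given an additional fixed effect
#'   (`major_effect` per alt-allele copy), e.g. a subpopulation-differentiated
#'   flowering-time locus that makes the trait bimodal.
#' @param major_effect Effect per allele copy of the major locus.
#' @param equal_large Give every large-effect QTL the same marginal variance
#'   share (random signs, magnitudes scaled per locus); with the default
#'   `FALSE` large effects are Normal draws, so shares vary.
#' @param seed RNG seed.
#'
#' @return A list of class `sim_truth`: `qtl` tibble (`marker_id`, `effect`,
#'   `class`), plus `h2`, `year_effect_sd`, `trait_name`, `major_locus_id`.
#' @export
plant_qtl <- function(geno, variants, n_large = 0L, n_small = 0L,
                      large_var_share = 0.5, h2 = 0.7, year_effect_sd = 1,
                      trait_name = "trait", major_locus_id = NULL,
                      major_effect = 10, equal_large = FALSE, seed = 1L) {
  assert_geno(geno)
  if (n_large < 0 || n_small < 0) abort("QTL counts must be >= 0")
  if (n_large + n_small > ncol(geno)) abort("more QTL requested than markers available")
  if (n_large > 0 && n_small > 0 &&
      (large_var_share <= 0 || large_var_share >= 1)) {
    abort("`large_var_share` must lie in (0, 1)")
  }
  if (h2 <= 0 || h2 > 1) abort("`h2` must lie in (0, 1]")
  if (!is.null(major_locus_id) && !major_locus_id %in% colnames(geno)) {
    abort("`major_locus_id` not found among markers")
  }
  with_seed(seed, {
    pool <- setdiff(colnames(geno), major_locus_id)
    ids <- if (n_large + n_small > 0) sample(pool, n_large + n_small) else character()
    cls <- rep(c("large", "small"), c(n_large, n_small))
    eff <- stats::rnorm(length(ids))
    if (equal_large && n_large > 0) {
      # same marginal variance for every large QTL: effect ~ 1/sd(dosage)
      sds <- apply(geno[, ids[cls == "large"], drop = FALSE], 2, stats::sd)
      eff[cls == "large"] <- sign(eff[cls == "large"]) / pmax(sds, 1e-12)
    }
    # rescale groups to the requested variance split, using realized variances
    gvar <- function(sel) {
      if (!any(sel)) return(0)
      stats::var(geno[, ids[sel], drop = FALSE] %*% eff[sel])[1]
    }
    if (n_large > 0 && n_small > 0) {
      vl <- gvar(cls == "large"); vs <- gvar(cls == "small")
      if (vl > 0) eff[cls == "large"] <- eff[cls == "large"] *
          sqrt(large_var_share / vl)
      if (vs > 0) eff[cls == "small"] <- eff[cls == "small"] *
          sqrt((1 - large_var_share) / vs)
    } else if (length(ids) > 0) {
      v <- gvar(rep(TRUE, length(ids)))
      if (v > 0) eff <- eff / sqrt(v)
    }
    qtl <- tibble::tibble(marker_id = ids, effect = as.numeric(eff), class = cls)
    if (!is.null(major_locus_id)) {
      qtl <- dplyr::bind_rows(qtl, tibble::tibble(
        marker_id = major_locus_id, effect = major_effect, class = "major"
      ))
    }
    structure(
      list(qtl = qtl, h2 = h2, year_effect_sd = year_effect_sd,
           trait_name = trait_name, major_locus_id = major_locus_id),
      class = "sim_truth"
    )
  })
}

#' True genetic values implied by a planted architecture
#'
#' @param geno Dosage matrix.
#' @param truth A [plant_qtl()] result.
#' @return Named numeric vector, one genetic value per line.
#' @export
genetic_values <- function(geno, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  if (nrow(truth$qtl) == 0) {
    return(stats::setNames(rep(0, nrow(geno)), rownames(geno)))
  }
  missing_ids <- setdiff(truth$qtl$marker_id, colnames(geno))
  if (length(missing_ids) > 0) {
    abort(sprintf("causal markers absent from genotype matrix: %s",
                  paste(utils::head(missing_ids, 3), collapse = ", ")))
  }
  drop(geno[, truth$qtl$marker_id, drop = FALSE] %*% truth$qtl$effect)
}

#' Simulate replicated multi-year phenotypes
#'
#' Each observation is `mu + genetic value + year effect + noise`. Year
#' effects are drawn once per year and shared by all lines (a common
#' environment the BLUP stage must absorb). Residual noise is scaled from the
#' realized genetic variance so the narrow-sense heritability of line means
#' matches `truth$h2` in expectation: per-observation residual variance is
#' `Vg * (1 - h2) / h2 * n_years * n_reps`.
#'
#' @param geno Dosage matrix.
#' @param truth A [plant_qtl()] result.
#' @param n_years,n_reps Years and replicates per year.
#' @param mu Trait intercept (e.g. 160 days for a flowering-time-like trait).
#' @param seed RNG seed.
#' @param null_sd Residual SD used when the architecture is empty (pure-noise
#'   trait).
#' @return Tibble `line_id, year, rep, trait, value` (long phenotype records).
#' @export
simulate_phenotypes <- function(geno, truth, n_years = 2L, n_reps = 2L,
                                mu = 0, seed = 1L, null_sd = 1) {
  assert_geno(geno)
  stopifnot(inherits(truth, "sim_truth"))
  assert_count(n_years, "n_years"); assert_count(n_reps, "n_reps")
  g <- genetic_values(geno, truth)
  vg <- stats::var(g)
  if (vg == 0 && truth$h2 >= 1) {
    abort("empty architecture with h2 = 1 requests zero noise on a constant trait")
  }
  r <- n_years * n_reps
  sd_e <- if (vg > 0) sqrt(vg * (1 - truth$h2) / truth$h2 * r) else null_sd
  with_seed(seed, {
    year_eff <- stats::rnorm(n_years, 0, truth$year_effect_sd)
    grid <- tidyr::expand_grid(
      line_id = rownames(geno),
      year = sprintf("Y%d", seq_len(n_years)),
      rep = seq_len(n_reps)
    )
    grid$trait <- truth$trait_name
    grid$value <- mu + g[grid$line_id] +
      year_eff[as.integer(sub("Y", "", grid$year))] +
      stats::rnorm(nrow(grid), 0, sd_e)
    grid
  })
}

#' Mask genotype calls at random
#'
#' Each entry is independently set missing with probability `rate`;
#' deterministic for a fixed seed.
#'
#' @param geno Dosage matrix.
#' @param rate Missingness probability in \[0, 1).
#' @param seed RNG seed.
#' @return The matrix with masked entries set to `NA`.
#' @export
inject_missing <- function(geno, rate, seed = 1L) {
  assert_geno(geno)
  if (rate < 0 || rate >= 1) abort("`rate` must lie in [0, 1)")
  if (rate == 0) return(geno)
  with_seed(seed, {
    geno[stats::runif(length(geno)) < rate] <- NA
    geno
  })
}

#' Pick the most subpopulation-differentiated marker
#'
#' Convenience selector for a major-locus candidate: the marker with the
#' largest alt-allele frequency gap between two subpopulations.
#'
#' @param panel A [simulate_population()] result.
#' @param pops Two subpopulation labels to contrast (defaults to the two
#'   largest).
#' @return A marker id.
#' @export
pick_major_locus <- function(panel, pops = NULL) {
  stopifnot(inherits(panel, "sim_panel"))
  tab <- sort(table(panel$subpops$subpop), decreasing = TRUE)
  if (is.null(pops)) pops <- as.integer(names(tab)[1:2])
  f <- lapply(pops, function(s) {
    alt_freq(panel$geno[panel$subpops$subpop == s, , drop = FALSE])
  })
  names(which.max(abs(f[[1]] - f[[2]])))
}
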