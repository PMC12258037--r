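# Small panels used across tests; all deterministic in `seed`.

small_panel <- function(seed = 1, n_per = c(60, 60), m_chr = 200, n_chr = 1,
                        divergence = 0.15, recomb = 2, maf_floor = 0.05) {
  simulate_population(sim_config(
    n_lines_per_subpop = n_per, n_chromosomes = n_chr,
    markers_per_chromosome = m_chr, chromosome_length_bp = 1e7,
    n_founder_haplotypes = 20, recombination_rate = recomb,
    subpop_divergence = divergence, maf_floor = maf_floor, seed = seed
  ))
}

# iid biallelic dosage matrix (no LD, no structure), lines x m
iid_geno <- function(n, m, seed = 1, maf_range = c(0.1, 0.5)) {
  withr::with_seed(seed, {
    p <- runif(m, maf_range[1], maf_range[2])
    g <- matrix(2 * rbinom(n * m, 1, rep(p, each = n)), n, m)
    dimnames(g) <- list(sprintf("L%04d", 1:n), sprintf("chr01_%d", seq_len(m) * 1000))
    # guard against monomorphic draws
    mono <- apply(g, 2, sd) == 0
    g[1, mono] <- 2 - g[1, mono]
    g
  })
}

iid_variants <- function(g) {
  tibble::tibble(
    marker_id = colnames(g), chrom = "chr01",
    pos = as.integer(sub("chr01_", "", colnames(g))),
    ref = "A", alt = "T",
    maf = pmin(colMeans(g) / 2, 1 - colMeans(g) / 2),
    missing_rate = 0, is_cds = FALSE, is_indel = FALSE
  )
}

# line means in panel order
line_means <- function(ph, geno) {
  as.numeric(tapply(ph$value, ph$line_id, mean)[rownames(geno)])
}
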