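---
title: "Methods: GWAS-assisted genomic prediction in structured breeding panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GWAS-assisted genomic prediction in structured breeding panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwaspred)
```

## Scope

`gwaspred` implements a complete desk-scale genomic-prediction study for a
structured crop breeding panel: simulate (or ingest) genotypes, derive
per-line BLUP phenotypes from replicated multi-year trials, characterize the
population (LD decay, windowed Fst, PCA, genetic distances), run a
kinship-corrected mixed-linear-model GWAS, build marker feature sets by GWAS
significance thresholds / PCA / CDS subsampling, and benchmark GBLUP,
Bayesian Lasso, kernel ridge, random-forest and boosted-tree predictors
under 10-fold cross-validation with Gaussian-process hyperparameter tuning.
The motivating system is a rapeseed (*Brassica napus*) diversity panel of
roughly 400 inbred lines split into three vernalization ecotypes; the
package's defaults mirror that structure (165/61/178 lines per
subpopulation, a flowering-time-like trait made bimodal by a
subpopulation-differentiated major locus, MAF > 0.05 and missingness < 10%
variant filters, a 52-kb QTL flank matching genome-wide LD decay at
r² = 0.2).

## The panel simulator

`simulate_population()` draws, per subpopulation, a pool of founder
haplotypes under the Balding–Nichols model: each marker has an ancestral
frequency `p0 ~ U(0.05, 0.95)` and subpopulation frequencies
`Beta(p0(1-F)/F, (1-p0)(1-F)/F)`, so the divergence parameter `F` is
approximately the expected Fst between subpopulations. Each inbred line is a
recombinant mosaic of two founder haplotypes from its own pool, doubled to
homozygosity (dosages 0/2; residual heterozygosity is an option).

Two design choices matter for linkage disequilibrium, and both were made
once, on first principles:

* **Crossovers accumulate over generations.** A single meiosis between two
  founders leaves adjacent-marker LD essentially independent of the
  recombination rate at realistic marker spacing. Lines in a breeding panel
  descend from their founders through many meioses, so the mosaic's
  crossover count is `Poisson(recombination_rate × n_generations)` with
  `n_generations = 10` by default. The LD decay scale is then
  `chromosome_length / (rate × generations)`, and decay distance responds
  monotonically to the rate — a property the test suite checks at rates
  0.5, 2 and 8.
* **A small founder pool sets baseline LD.** Markers on an unbroken founder
  segment share an r² of roughly `1/(n_founders − 1)` across the panel —
  the pool plays the role of local haplotype redundancy in real panels. The
  default of 5 founders per subpopulation gives a baseline adjacent-marker
  r² near 0.25, so the decay curve starts above the conventional r² = 0.2
  threshold, as in dense real panels. Studies that need a low-LD panel
  (e.g. marker-effect recovery) raise `n_founder_haplotypes` instead.

`plant_qtl()` samples causal markers and scales effects against the
*realized* dosage variance of this sample, so the bookkeeping identity
`var(Σ effects × dosage) = Vg` holds exactly and small panels hit their
target architecture without Monte-Carlo drift. `large_var_share` splits the
genetic variance between a "large" and a "small" QTL class;
`equal_large = TRUE` additionally equalizes the marginal variance of every
large QTL (random signs), which is the configuration used for power
studies. `simulate_phenotypes()` adds a year effect drawn once per year and
shared by all lines (a common environment that the BLUP stage must absorb)
plus residual noise scaled so the narrow-sense heritability **of line
means** equals the target `h2`; with `n_years × n_reps` observations per
line the per-observation residual variance is `Vg (1−h2)/h2 × n_years ×
n_reps`.

What the simulator does *not* emulate: sequence-level mutation, a realistic
site-frequency spectrum, crossover interference, genotype-by-environment
interaction, and selection. Tests passing on these panels show the
pipeline's statistics behave correctly under a known truth; they are not a
claim about any particular real data set.

## BLUP phenotypes

`fit_blup()` fits `value ~ year + (1 | line)` by REML through `lme4` (year
fixed, replicate absorbed in the residual; `(1|year)` is a switch). The
reported BLUP is the average fixed-effect prediction plus the line's
shrunken random effect; for a balanced design this reduces to the textbook
shrinkage `μ + (σ²_line/(σ²_line + σ²_e/r))(ȳ_i − μ)`, which the tests use
as an independent oracle at 1e-8. Plot-level records are assumed (rather
than replicate means); with a balanced design the two differ only in the
residual-variance bookkeeping.

## Population characterization

* **LD** is the squared Pearson correlation of dosage vectors (composite
  LD) — appropriate for unphased, imputed, essentially homozygous panels.
  `ld_decay()` bins all within-chromosome pairs by distance, smooths the
  binned means by decreasing isotonic regression (protecting the threshold
  crossing from noisy early bins; raw crossing available), and reports the
  linear interpolation of the first crossing below r² = 0.2. A curve that
  never crosses yields `Inf`; one already below threshold yields the first
  bin midpoint.
* **Fst** uses the Weir–Cockerham (1984) estimator with windows summarized
  as ratio-of-sums (the "weighted" convention used by common VCF tooling);
  a per-site mean is available. Observed heterozygote proportions enter the
  formulas, so residual heterozygosity is handled.
* **PCA** standardizes markers by allele frequency (center `2p`, scale
  `sqrt(2p(1−p))`) and takes scores from the SVD; monomorphic markers are
  dropped and counted.
* **Genetic distance** is the mean absolute dosage difference over shared
  non-missing markers, divided by 2 (a p-distance in [0, 1]); tree building
  is deliberately out of scope.

## Mixed-model GWAS

The association scan follows the EMMAX strategy. `vanraden_grm()` builds
`G = ZZ'/(2Σp(1−p))`; for fully inbred panels the diagonal is near 2
(1 + inbreeding). `reml_null()` eigendecomposes K once and maximizes the
restricted likelihood over `log δ` (`δ = σ²_e/σ²_g`) on [1e−5, 1e5] by
Brent search; `mlm_scan()` then tests every marker by weighted least
squares on the rotated data with δ fixed, using a t reference distribution
with `n − q − 1` degrees of freedom. Fixed covariates default to an
intercept plus the first three genotype PCs. Markers collinear with the
covariates are flagged and given p = 1 rather than dropped.

`lambda_gc()` is the median 1-df chi-square quantile over 0.4549364. On
two-subpopulation polygenic nulls the naive scan inflates enormously
(λ ≈ 10) while the mixed model stays within [0.9, 1.1] — the core
false-positive-control claim, checked over 10 seeds.

`call_qtl()` groups significant markers (−log10 p ≥ 6, inclusive) within a
flank distance, takes the smallest-p marker as peak (ties to the smaller
coordinate) and reports `peak ± flank` clamped at 1; the 52-kb default
matches the LD-decay convention above. `effective_markers()` implements the
Li & Ji eigenvalue count per chromosome as the effective-test proxy; the
fixed −log10 p ≥ 6 threshold is the default policy and a Bonferroni-on-Me
policy (α/Me) can be built from it — the "one-tenth of Me" phrasing used
with effective-marker software is ambiguous between α-scaling and an index,
so the package exposes Me itself and keeps the fixed threshold as default.
`trait_overlap()` uses a strict threshold (−log10 p > 3) and reports both
plain and exclusive (upset-style) intersection counts per trait subset.

## Feature sets and selection leakage

`threshold_features()` keeps markers at or above a −log10 p cutoff
(inclusive, so "3P" contains exactly-3.0 markers; strict mode available);
sets are nested across cutoffs by construction. `pca_features()` keeps the
smallest number of components reaching 95% cumulative explained variance.
`cds_features()` takes every 20th CDS SNP in positional order from a seeded
random offset — systematic sampling; a Bernoulli 1-in-20 mode is the flag
alternative. InDels are excluded from CDS sets; the threshold sets carry
both variant classes through.

Selecting markers by a whole-panel GWAS *before* cross-validation leaks the
held-out lines' phenotypes into the features. Both modes are first-class:
passing a `feature_set` to `cross_validate()` reproduces the whole-panel
protocol, while passing a selector function (see `threshold_selector()`)
re-runs the scan inside each training fold. On null traits the whole-panel
mode shows clearly positive "accuracy" while the within-fold mode stays at
zero — the test suite demonstrates both, and the benchmark results should
be read with that distinction in mind.

## Prediction models

* **GBLUP** is implemented from the mixed-model formulas (G on stacked
  train+test rows, δ REML-estimated per training fold to avoid leakage, GLS
  intercept, kriging-style prediction). Under the VanRaden scaling it
  equals ridge regression on centered dosages with penalty
  `λ = δ · 2Σp(1−p)`; an independently coded primal ridge is the
  equivalence oracle at 1e-6.
* **Bayesian Lasso** is the Park–Casella Gibbs sampler (normal conditional
  for effects, inverse-Gaussian for the local scales, Gamma for λ², scaled
  inverse-χ² for σ²), coded in C++ with coordinate-wise effect updates and
  R's RNG for seed-reproducibility. The chain starts at dimension-scaled
  strong shrinkage (λ² = m): with weak initial shrinkage and more markers
  than lines the hierarchy admits a degenerate interpolation mode (σ² → 0)
  that null data never escape. A genuine limitation remains: in m ≈ n null
  regimes the posterior keeps nontrivial effect mass, so "null effects are
  almost zero" holds only as shrinkage relative to least squares, and the
  package's tests assert exactly that.
* **KRR** is the closed-form RBF dual solve with column standardization.
* **RF** delegates to `ranger`, **GBDT/XGBoost/LightGBM** are presets of
  one boosted-tree regressor backed by the `xgboost` engine (depth-wise
  exact trees vs a leaf-limited histogram profile), single-threaded for
  determinism. Tree predictions are location-equivariant only up to
  floating-point split tie-breaks; the linear models are equivariant to
  1e-8.

Hyperparameter bounds follow the study conventions: regularization 1–500,
RBF bandwidth 1e-5–1e-3 (log scale), 20–200 trees, depth 5–25, learning
rate 0.01–0.1.

## Evaluation

`kfold_split()` produces shuffled folds differing by at most one in size;
`pearson_accuracy()` is the plain Pearson correlation between observed and
predicted values of held-out lines (accuracy is computed against observed
BLUP phenotypes, the unambiguous reading when predictions are compared to a
"GEBV" target). `bayes_opt()` is a Matérn-5/2 Gaussian-process
expected-improvement optimizer: Latin-hypercube initialization, length
scale chosen by marginal likelihood over a coarse grid each iteration,
acquisition maximized over random candidates, log-scale and integer
dimensions supported, failures recorded and skipped. The conventional full
budget is 20 initial points plus 280 iterations; tests and examples use
20 + 30, which already recovers a known 1-D optimum on [1, 500] within ±5.
`benchmark_grid()` crosses models with feature sets and emits the long-form
accuracy table.

## Problem sizes and numerical choices

Simulated studies in the tests and in `scripts/acceptance.R` use panels of
300–500 lines and 2 000–5 000 markers over 2–10 chromosomes of 2×10⁷ bp —
sizes at which every claim runs in seconds to a couple of minutes on one
core. Two artifacts of aggressive scale-down are worth knowing. First, with
m = 5000 markers on few chromosomes the LD blocks are so long that the
kinship term absorbs much of a single QTL's signal; power studies therefore
spread markers over 10 chromosomes. Second, even so, a QTL carrying 7% of
phenotypic variance at n = 400 has an exact OLS detection power of ~0.70
at p ≤ 1e-6 (noncentral t), so oligogenic recovery rates around 55–65%
under the mixed model are the honest expectation at this scale, not a
defect of the scan.

Other numerics: REML tolerance 1e-6 on log δ with a 1e-8 PSD jitter on K;
isotonic smoothing before LD threshold crossing; mode imputation ties break
to the lower dosage; BED intervals are 0-based half-open, all internal
coordinates 1-based inclusive; multiallelic VCF records are rejected by
default; QTL peak ties break to the smaller coordinate.

## Known limitations

Single-trait models only (no multi-trait BLUP, no G×E); no haplotype-model
imputation (mode imputation is the deterministic default for inbred
panels); no admixture-model structure analysis or tree rendering; the
boosted-tree presets approximate, not emulate, the external boosting
systems; and the simulator's LD model is a founder-mosaic caricature —
adequate for testing monotone relationships and estimator calibration, not
for reproducing any specific genome's LD landscape.
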