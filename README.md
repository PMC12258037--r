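# gwaspred

GWAS-assisted genomic prediction for structured crop breeding panels.

Breeders predicting complex traits (flowering time, oil content, yield
components) from genome-wide markers face a feature-selection question:
resequencing yields millions of variants, most of them redundant for
prediction. `gwaspred` implements the full study design around that
question for a diversity panel of inbred lines — modeled on a rapeseed
(*Brassica napus*) panel of ~404 worldwide accessions in three
vernalization ecotypes — as a tested, reusable R pipeline:

* a **panel simulator** with known truth: Balding–Nichols subpopulation
  divergence, founder-haplotype mosaics with tunable LD decay, oligogenic
  or polygenic trait architectures, calibrated heritability, multi-year
  replicated phenotypes, and an optional subpopulation-differentiated major
  locus that makes a flowering-time-like trait bimodal;
* **genotype I/O**: VCF in/out, MAF > 0.05 and missingness < 10% filters,
  mode/mean/kNN imputation, CDS annotation from BED, 012 dosage matrices;
* **BLUP phenotypes** from `value ~ year + (1|line)` REML fits (lme4),
  with trait summaries and correlations;
* **population characterization**: dosage-LD decay with isotonic smoothing
  and the r² = 0.2 decay distance, sliding-window Weir–Cockerham Fst
  (20 kb / 5 kb), allele-frequency-standardized genotype PCA, p-distances,
  LD pruning;
* an **EMMAX-style mixed-linear-model GWAS**: VanRaden kinship, one-time
  eigendecomposition and 1-D REML for the variance ratio, per-marker
  weighted least squares, genomic-inflation diagnostics, Li & Ji effective
  marker counts, QTL-region calling at −log10 p ≥ 6 with a 52-kb flank,
  haplotype t-tests, cross-trait overlap counts;
* **feature builders**: GWAS-threshold marker sets (3P…5P, nested),
  PCA-to-95% scores, systematic 1-in-20 CDS SNP subsampling — with
  whole-panel and leakage-free within-fold selection both first-class;
* a **model bench** behind one fit/predict contract: GBLUP (mixed-model
  formulas, RR-BLUP-equivalent), Bayesian Lasso (Park–Casella Gibbs in
  C++), RBF kernel ridge, random forest (ranger), and boosted-tree presets
  (xgboost engine); plus 10-fold cross-validated Pearson accuracy, a
  Matérn-5/2 Gaussian-process Bayesian hyperparameter optimizer, and a
  model × feature-set benchmark grid.

At its core are two quantities. GBLUP predicts held-out genetic values from
the genomic relationship matrix `G = ZZ'/(2Σpⱼ(1−pⱼ))`:

    ĝ_test = G_test,train (G_train,train + δI)⁻¹ (y_train − μ̂),  δ = σ̂²ₑ/σ̂²_g

and the association scan tests each marker in `y = Qb + xβ + g + e`,
`g ~ N(0, σ²_g K)`, with δ fixed from the null model (EMMAX). Prediction
accuracy is the Pearson correlation between predicted and observed BLUP
phenotypes of held-out lines under 10-fold cross-validation.

## Worked example

Simulate the default panel (404 lines, 165/61/178 split across three
subpopulations), plant a bimodal flowering-time-like trait, derive BLUPs,
scan, select features, and cross-validate:

```r
library(gwaspred)

pan <- simulate_population(sim_config(seed = 42))
pan
#> <sim_panel> 404 lines x 1000 markers, 3 subpopulations (165/61/178)

major <- pick_major_locus(pan)   # most subpop-differentiated marker
truth <- plant_qtl(pan$geno, pan$variants, n_large = 2, n_small = 60,
                   h2 = 0.8, major_locus_id = major, major_effect = 10,
                   trait_name = "FT", seed = 7)
records <- simulate_phenotypes(pan$geno, truth, mu = 160, seed = 8)

blups <- fit_blup(records)
summarize_traits(blups)
#> # A tibble: 1 × 6
#>   trait   max   min  mean variance    sd
#>   <chr> <dbl> <dbl> <dbl>    <dbl> <dbl>
#> 1 FT     189.  150.  170.     94.4  9.72
```

The mean of ~170 days with peaks near 160 and 180 reflects the major locus
separating the subpopulations. Scan with kinship and 3 PCs, call QTL with
the 52-kb LD flank, and compare GWAS-selected markers to the whole panel:

```r
y <- blup_wide(blups)$FT[match(rownames(pan$geno), blup_wide(blups)$line_id)]
K <- vanraden_grm(pan$geno)
Q <- cbind(1, genotype_pca(pan$geno)$scores[, 1:3])
scan <- mlm_scan(pan$geno, reml_null(y, K, Q), pan$variants)

call_qtl(scan, threshold_neg_log10_p = 6, flank_bp = 52000)[, 1:6]
#> # A tibble: 1 × 6
#>   chrom peak_pos   peak_p   start     end n_markers
#>   <chr>    <int>    <dbl>   <dbl>   <dbl>     <int>
#> 1 chr01  2708216 1.46e-24 2656216 2760216         1

fs <- threshold_features(pan$geno, scan, 3, trait = "FT")
fs
#> <feature_set> threshold (parameter 3): 404 lines x 4 features

cross_validate(fs, y, gp_model("GBLUP"), k = 10, seed = 1)
#> <cv_report> GBLUP, 10 folds: mean r = 0.909 (SD 0.015)
cross_validate(pan$geno, y, gp_model("GBLUP"), k = 10, seed = 1)
#> <cv_report> GBLUP, 10 folds: mean r = 0.879 (SD 0.021)
```

Four GWAS-selected markers predict this oligogenic trait slightly better
than all 1000 — the marker-preselection effect the package is built to
study. Note that selecting features on the whole panel before
cross-validation leaks information; pass a selector function (see
`threshold_selector()`) for the leakage-free protocol, and see the methods
vignette (`vignettes/gwaspred-methods.Rmd`) for when each is appropriate.

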