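# radiosig

Radiogenomic analysis of cell-line radiation response: who survives
irradiation, which biology drives it, and can gene expression predict it.

`radiosig` is aimed at preclinical radiation-oncology and radiogenomics
analysts working with panels of irradiated cancer cell lines for which both
clonogenic dose–response data and genome-wide expression profiles are
available (a large discovery panel and an independent validation panel). It
covers four linked tasks:

1. **Radiobiological modelling.** Each cell line's survival data are fitted
   to the linear-quadratic (LQ) model

   *S(D) = exp(−αD − βD²)*

   with α (Gy⁻¹) the single-hit killing coefficient and β (Gy⁻²) the
   double-strand-break interaction term, by non-negative linearized least
   squares on −ln S (no intercept, so S(0) = 1). Two radioresponse
   indicators are derived: **SF2** = S(2 Gy), the classical point estimate,
   and **AUC** = ∫₀^dmax S(D) dD (Gy), the integral of the fitted curve over
   the administered dose range. Higher AUC = more radioresistant; cohorts
   are stratified at the mean AUC.
2. **Biological determinants.** Genes are ranked by Spearman correlation
   with AUC (or SF2); each pathway in a gene-set collection receives a
   weighted Kolmogorov–Smirnov running-sum enrichment score (ES = signed
   maximum deviation from zero), a gene-label permutation p-value with
   add-one correction, and a Benjamini–Hochberg FDR within the collection.
   Pathways enriched by AUC vs SF2 are compared by set algebra, and the
   leading-edge genes (hits up to / after the running-sum extremum) are
   extracted and intersected across indicators.
3. **Predictive signature.** After an optional radioresponse-compendium
   prefilter, the top-k genes by |Spearman ρ| with AUC enter a multivariate
   linear model on z-scored expression (minimum-norm solution for
   rank-deficient designs). Performance is the concordance index
   (0.5 = random, 1 = perfect; prediction ties 0.5, outcome ties excluded)
   under repeated k-fold cross-validation in which feature selection and
   fitting are re-run inside every training fold, followed by a single
   external validation on the independent cohort (z-scored within-cohort to
   absorb the platform gap).
4. **Synthetic cohorts.** A seeded simulator generates
   discovery/validation pairs with known LQ parameters, multiplicative
   lognormal survival noise, AUC-coupled signal genes shared across cohorts
   and planted/null pathway collections, so every stage is testable end to
   end with ground truth.

## Worked example

```r
library(radiosig)

cfg  <- simulation_config(n_discovery = 120, n_validation = 40, n_genes = 500,
                          n_signal_genes = 30, seed = 42)
disc <- generate_cohort(cfg, "discovery")
val  <- generate_cohort(cfg, "validation")

fits <- fit_cohort(disc$dose_response)
fit_lq(disc$dose_response[[1]])
#> LQ fit [DIS_001]: alpha = 0.3306 /Gy, beta = 0.0254 /Gy^2, AUC = 2.305 Gy,
#> SF2 = 0.466 (n = 6, rss = 0.0671)

cv <- cross_validate(disc$expression, fits$auc, k_grid = c(5, 10, 20, 30),
                     n_folds = 10, n_repeats = 5, seed = 42)
cv
#> 5 x 10-fold CV: best k = 30, mean concordance = 0.865 (95% CI 0.838-0.891)

model <- build_signature(disc$expression, fits$auc, cv$best_k)
external_validate(model, val$expression, fit_cohort(val$dose_response)$auc)
#> [1] 0.8957

gs  <- generate_genesets(disc, n_planted = 3, n_null = 12, set_size_range = c(10, 20))
enr <- enrich_collection(disc$expression, fits$auc, gs, n_perm = 500, seed = 42)
head(enr[order(enr$fdr), c("pathway", "es", "p_nominal", "fdr", "direction")], 5)
#>     pathway         es   p_nominal        fdr direction
#>  PLANTED_01 -0.9304448 0.001996008 0.00998004  negative
#>  PLANTED_02  0.9846708 0.001996008 0.00998004  positive
#>  PLANTED_03 -0.9761327 0.001996008 0.00998004  negative
#>     NULL_01  0.3899381 0.465069860 0.90153027  positive
#>     NULL_02  0.3854068 0.445109780 0.90153027  positive
```

The first line is the LQ fit of one cell line: its α/β ≈ 13 Gy and AUC of
2.3 Gy over the 0–8 Gy range mark it as moderately radiosensitive. The CV
block reports the signature size chosen by cross-validation and the
pre-validation concordance with its 95% CI over repetitions; the external
concordance (0.90) shows the signature transfers to the independent cohort
because the simulated signal genes are shared. The enrichment table ranks
pathways by FDR: the three planted pathways are recovered at the p-value
floor with the correct directions, the null sets are not.

Real cohorts are read from plain-text formats instead of simulated:
`read_dose_response()` (CSV: `cell_line,tissue,dose_gy,survival`),
`read_expression()` (TSV, genes × samples), `read_gmt()` (pathway
collections) and `read_gene_list()` (compendium); `pipeline_config()` +
`run_pipeline()` chain all stages and write TSV/JSON outputs with a
provenance manifest.

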