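# pubbias

Detecting and correcting publication bias in multilevel meta-analytic
corpora, and quantifying its downstream damage: shrinkage of effect sizes,
loss of statistical power, and inflation of Type M (exaggeration) and
Type S (sign) errors.

The package is written for meta-researchers and meta-analysts working with
effect-size corpora — many meta-analyses, each holding effect sizes (SMD,
lnRR, or Fisher's Zr) nested within primary studies — who want to run the
whole analysis chain reproducibly:

1. **Multilevel meta-analysis.** Intercept-only three-level model
   `ES_ji = β0 + s_j + o_ji + m_ji` fitted by REML with known sampling
   variances, Wald-z inference, multilevel I² (`fit_multilevel`,
   `wald_inference`, `heterogeneity_stats`).
2. **Bias detection.** Multilevel Egger-type meta-regression of effect size
   on its uncertainty (effective-sample predictor `√((n_e+n_c)/(n_e n_c))`
   for SMD/lnRR where group sizes exist, else the standard error) and on
   year centred at the latest publication year: `β1` flags small-study
   effects, `β2` decline effects (`fit_bias_models`).
3. **Bias correction.** The quadratic-uncertainty model's intercept,
   conditional on zero sampling error at the latest year, with a sign-based
   decision tree that drops slope terms whose direction contradicts a
   selection explanation (`apply_decision_tree`, `analyze_meta`).
4. **Second-order meta-analysis.** Per-case standardization (response
   divided by its SD; shifted z-scaled predictors) and random-effects
   pooling of the standardized slopes across meta-analyses, with an
   effect-size-type moderator, τ², I², and marginal R²
   (`standardize_case`, `pool_coefficients`).
5. **Shrinkage.** Folded-normal mean/variance of the absolute difference
   between uncorrected and corrected standardized effects, pooled and
   back-transformed to original units (`difference_and_fold`,
   `pool_differences`, `backtransform`).
6. **Retrodesign.** Closed-form power, Type M, and Type S errors from
   truncated-normal expectations, with a seeded Monte-Carlo oracle, and
   aggregation at the primary-study level (study-random-intercept model)
   and the meta-analysis level (k-weighted regression)
   (`design_metrics`, `retrodesign_mc`, `aggregate_*`).
7. **Synthetic literatures.** A generator with known ground truth —
   hierarchical effects, realistic estimate–variance coupling from
   simulated summary statistics, significance-driven selection, optional
   time-relaxing selection that induces a decline effect
   (`generator_config`, `generate_corpus`, `apply_selection`).

`run_pipeline()` chains steps 1–6 over a corpus; the numbered scripts under
`analysis/` run the whole study (simulate → per-meta models → second-order
pooling → shrinkage → power/errors) and write tables under `results/`.

## Worked example

```r
library(pubbias)

# a biased literature: true effect 0.1, harsh selection against
# non-significant results
cfg <- generator_config(n_meta = 10, studies_per_meta = 40, metric = "SMD",
                        mu = 0.1, selection_strength = 2,
                        group_size_range = c(5, 80), seed = 1)
corpus <- generate_corpus(cfg)$corpus
bundle <- run_pipeline(corpus)

round(bundle$pooled$eta1$full$estimate, 3)   # pooled small-study slope
#> [1] 0.223
round(bundle$pooled$eta1$full$pval, 4)
#> [1] 0.0064
round(mean(bundle$cases$beta0_overall), 3)   # inflated naive means
#> [1] 0.264
round(bundle$pooled_D$reduced$estimate, 3)   # shrinkage, SD units
#> [1] 0.527
round(100 * bundle$aggregates[["sampling.uncorrected.power"]]$mean)
#> [1] 22
round(100 * bundle$aggregates[["sampling.corrected.power"]]$mean)
#> [1] 12
```

Read: the pooled standardized small-study slope is positive and
significant (selection detected); the naive overall means average 0.264
against a true 0.1 (inflation); correcting shifts the standardized effects
by ~0.53 SD; and primary-study power drops from 22% to 12% once the
bias-corrected effect is used as the truth proxy — exactly the pattern a
selective-publication process imprints.

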