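# sparsepgs

Sparse polygenic score (PGS) construction, evaluation and biobank
projection in R.

## The problem

A linear polygenic score summarizes a genotype into one number,
`PGS = X · β`, with `X` the matrix of SNP dosages (0/1/2 counts of an
effect allele) and `β` per-SNP weights learned from genotype–phenotype
data. Sparse learners — the LASSO and the elastic net — activate only a
small subset of SNPs, which matters for interpretability, genotyping cost
and cross-ancestry transport. Two questions dominate planning for such
predictors:

1. **How does performance grow with training data**, and what is the best
   a given trait will ever achieve (the infinite-data asymptote)? This
   decides whether a planned biobank is worth recruiting.
2. **How sparse is the trait really**, and when does the learner cross
   the compressed-sensing (Donoho–Tanner) phase transition — the training
   size at which L1 methods suddenly recover the causal SNP set?

`sparsepgs` implements the full pipeline for studying both at desk scale,
with a synthetic biobank generator standing in for access-controlled
cohort data: genotype simulation (Hardy–Weinberg with configurable MAF
spectrum, optional AR(1)-copula LD blocks, Balding–Nichols ancestry
drift, full-sibling pairs), sparse additive architectures with exact
in-sample heritability, liability-threshold case-control traits, QC and
covariate adjustment, elastic-net regularization paths over nested
training-size ladders with validation-set hyperparameter selection and
cross-validation, the standard metric suite, sparsity/phase-transition
diagnostics, and growth-curve projection with Monte-Carlo bands.

## The core models

**Training objective** (elastic net; `r = 1` is the LASSO):

    (1/2N) ‖y_adj − Xβ‖₂² + λ ( r‖β‖₁ + (1−r)/2 ‖β‖₂² )

solved along a descending log-spaced λ path from
`λ_max = max|Xᵀy|/(N r)`, with hyperparameters picked by validation-set
AUC (binary) or correlation (continuous).

**Single SNP variance** (no-covariance approximation to the score
variance): `SSV = Σᵢ 2βᵢ²fᵢ(1−fᵢ)`.

**Liability threshold**: an individual is a case when the standard-normal
liability exceeds `qnorm(1 − prevalence)`.

**Growth families**: metric-vs-size curves are fit by four bounded
4-parameter forms `g(x) = a + b·u(c(x+d))`, `x = log₁₀(N)`, with `u` ∈
{logistic, atan, erf, tanh}, under the physical constraints
`0.5 ≤ a−b`, `a+b ≤ 1` (AUC; 0/1 for correlation), `b, c > 0`, `d ≤ 0`.
The asymptote `a + b` is the infinite-data metric; parameter uncertainty
propagates through Cholesky-sampled Monte-Carlo bands.

## Worked example

Simulate a continuous trait with heritability 0.5 from 10 causal SNPs
among 500, train a LASSO over an 8-rung nested ladder with 2-fold
cross-validation, and project the correlation to a larger cohort:

```r
library(sparsepgs)

cfg  <- sim_config(n_samples = 4000, n_snps = 500, n_causal = 10, h2 = 0.5,
                   effect_dist = "equal", seed = 42)
geno <- simulate_genotypes(cfg)
arch <- simulate_architecture(geno, cfg)
qc   <- qc_filter(geno)

tcfg <- train_config(l1_ratio = 1, n_folds = 2, n_rungs = 8,
                     ladder_min = 100, validation_size = 250,
                     top_k = 500, seed = 42)
cv    <- cv_train(qc$genotypes, arch$phenotype, "continuous", tcfg)
curve <- metric_curve(cv)
curve
#>      N  value     se n_active n_folds
#> 1  100 0.4005 0.0272     28.5       2
#> 2  151 0.5508 0.0199     47.5       2
#> 3  227 0.6111 0.0257     57.5       2
#> 4  341 0.6844 0.0159     28.5       2
#> 5  513 0.6934 0.0117     21.5       2
#> 6  772 0.7063 0.0129     29.5       2
#> 7 1163 0.7148 0.0111     21.0       2
#> 8 1750 0.7143 0.0110     53.0       2
```

The test correlation climbs toward the heritability ceiling
`√h² ≈ 0.707` as training size grows; `n_active` is the number of SNPs
with non-zero weights in the selected predictor at each rung. Fit all
four growth families and pool their asymptotes:

```r
fits   <- lapply(growth_families(), function(f) fit_growth(curve, f, "correlation"))
pooled <- combine_families(fits)
#> pooled asymptote: 0.715 (95% CI 0.692-0.739)

band <- mc_band(fits[[3]], seed = 42)        # erf family
project_biobank(band, 5e4)
#> projected correlation at N = 50000: 0.712 (95% band 0.697-0.724)
```

The pooled infinite-data asymptote (0.715) brackets the true ceiling
0.707, and a 50,000-sample cohort is projected to sit essentially at that
plateau — i.e. for this architecture, most of the achievable signal is
already captured at a few thousand training samples.

Phase-transition behavior (the sharp metric jump as the ladder crosses
the sparse-recovery threshold) is exposed by:

```r
r <- phase_transition_sim(s = 20, p = 2000, h2 = 0.5, seed = 1)
r$N_star      # detected transition training size (geometric midpoint)
#> [1] 367
```

A command-line wrapper for full pipeline runs is installed as
`exec/sparsepgs` (`sparsepgs run --config cfg.yaml --out rundir`).

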