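---
title: "Sparse polygenic scores: models, training ladders and biobank projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse polygenic scores: models, training ladders and biobank projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsepgs)
```

## The problem

A polygenic score (PGS) summarizes a person's genotype into a single number,
`PGS = X . beta`, where `X` holds SNP dosages (counts of an effect allele,
0/1/2) and `beta` is a vector of per-SNP weights learned from
genotype--phenotype pairs. Sparse learners — the LASSO and the elastic net —
produce weights in which only a small number of SNPs are active, which makes
predictors cheaper to genotype, easier to interpret, and easier to transport
across ancestry groups.

`sparsepgs` implements the full life cycle of such predictors at desk scale:

1. **simulate** biobank-like genotypes and phenotypes with known ground
   truth;
2. **preprocess** (quality control, sex-specific z-scoring, covariate
   adjustment, GWAS-based SNP pre-filtering);
3. **train** penalized regression paths over a ladder of training sizes with
   cross-validation and validation-set hyperparameter selection;
4. **evaluate** with the field's metric suite (AUC, correlation, inclusive
   odds ratios, sibling selection tests, single-SNP variance,
   variance-explained estimates);
5. **sparsity**: characterize how the active SNP set grows with training
   size and detect compressed-sensing phase-transition behavior;
6. **project** metric growth to larger cohorts with Monte-Carlo uncertainty
   bands.

Real biobank genotypes are access-controlled, so the simulator is a
first-class, tested component: every downstream stage is validated against
architectures whose causal SNPs, effect sizes and heritability are known
exactly.

## The synthetic-data generator

**Genotypes.** Per-SNP effect-allele frequencies are drawn uniformly on
`[maf_low, maf_high]` (default `[0.01, 0.5]`) and dosages are binomial
`Bin(2, f)` under Hardy-Weinberg equilibrium. Real SNP panels have a
U-shaped frequency spectrum and long-range LD; the uniform spectrum and
(default) independent SNPs are deliberate simplifications — the theory the
package probes (sparse recovery, learning-curve growth) is stated for the
independent-SNP regime. Optional LD blocks are generated by an AR(1)
Gaussian copula on the latent haplotype liabilities: each of the two
haplotypes per individual carries an AR(1)-correlated standard-normal
vector thresholded at `qnorm(f)`, which preserves Hardy-Weinberg marginals
while inducing within-block dosage correlation. The implied dosage
correlation is the bivariate-normal orthant probability expression, which
the test suite checks by quadrature.

**Architectures.** `n_causal` SNPs are chosen without replacement; effects
are drawn on the standardized-genotype scale and the genetic value `G` is
rescaled so its in-sample variance equals `h2` *exactly*, with environment
`E ~ N(0, 1 - h2)` drawn independently. This makes parameter-recovery tests
sharp: under `P = G + E` the identity `h2 = corr(P, G)^2` holds up to the
sampling noise of `E` alone.

Two effect-magnitude models are provided. `effect_dist = "normal"` (the
default) draws standard-normal effects — a generic polygenic architecture
in which a few SNPs carry much of the signal. `effect_dist = "equal"` gives
every causal SNP the same magnitude with a random sign, the canonical
compressed-sensing benchmark. The distinction matters for the
phase-transition experiments: with normal effects the largest effects are
recoverable far below the transition, so the test metric grows smoothly and
the detected jump drifts toward small N; with equal effects no SNP is
individually easy, and recovery turns on sharply near the theoretical
threshold. `phase_transition_sim()` therefore uses `"equal"`.

**Case-control traits.** The continuous phenotype is treated as a liability
on the standard-normal scale; an individual is a case when the liability
exceeds `qnorm(1 - prevalence)`, so the realized case fraction converges to
the requested prevalence.

**Siblings.** Full-sibling pairs are generated by fair Mendelian
transmission: each offspring receives, independently at every SNP, one
allele per parent with probability `dosage / 2`. Both sibs share the same
two parents, giving the classical expected additive-genotype correlation of
0.5 (verified in the tests across 1,000 pairs). There is no recombination
map — transmissions are independent across SNPs, which is exact for
unlinked SNPs and an approximation inside LD blocks.

**Ancestry drift.** A second population is emulated by Balding-Nichols
drift: `f' ~ Beta(f(1-F)/F, (1-f)(1-F)/F)` per SNP, so `E(f') = f` and
`var(f') = F f(1-f)`. This captures allele-frequency divergence only — not
LD differences or effect-size heterogeneity — so cross-ancestry fall-off in
the simulator is a lower bound on the mechanisms present in real data.

**Randomness.** All stages derive independent streams from one master seed
(a fixed per-stage offset scheme), so identical configurations are
bit-reproducible and stages can be re-run in isolation.

## Preprocessing

Quality control applies the standard array filters in a fixed order — SNP
missingness > 3%, then sample missingness > 3%, then minor allele frequency
< 0.001 recomputed on the surviving samples — and mean-imputes the
remaining missing dosages. The order is fixed (the filters themselves are
standard but order-dependent) and the filter is idempotent.

Continuous phenotypes are z-scored within each sex separately, under the
assumption that the genetic factors sought are shared across sexes; this
roughly doubles usable training data relative to single-sex analyses. The
per-sex means and SDs are retained so the scoring can be inverted later.
Phenotypes are then residualized on covariates by least squares,
`y_adj = y - H alpha`, so the predictors capture *purely genetic* signal;
`y_adj` is orthogonal to the covariate space by construction.

The GWAS pre-filter (simple linear regression per SNP, top-k by p-value
with deterministic tie-breaking) is always computed on the training subset
of the current fold and rung, never on validation or test samples — the
filter is part of the learner, and computing it on held-out data would leak
information into the reported metrics. Binary traits use the same linear
score test on the labels: the output is a ranking for subsetting, not
inference.

## Training

The elastic net minimizes

$$
\frac{1}{2N}\lVert y_{adj} - X\beta\rVert_2^2
  + \lambda\left( r\,\lVert\beta\rVert_1
  + \frac{1-r}{2}\lVert\beta\rVert_2^2 \right),
$$

with mixing weight `r = l1_ratio` (1 = LASSO) over a descending
log-spaced path of 100 penalties from `lambda_max = max|X'y| / (N r)` (the
smallest penalty at which `beta = 0` satisfies the KKT conditions) down to
`lambda_max / 1000`. Path solving is delegated to the coordinate-descent
engine of **glmnet**; two corrections keep the solutions faithful to the
objective as stated:

* glmnet internally standardizes the response, which silently rescales the
  ridge component of the penalty by `sd(y)`. `enet_path()` feeds glmnet a
  unit-variance response with the mixing weight and penalty grid
  transformed so the returned coefficients minimize the objective above at
  the requested `(lambda, r)`.
* glmnet's stopping rule leaves coefficient errors around `1e-5` on
  elastic-net problems. A compiled active-set coordinate-descent refinement
  (`src/cd_refine.cpp`) drives every sparse-regime solution to KKT
  residuals below `1e-10`, then re-checks all coordinates for violators.
  Solutions in the deep-overfit tail (active sets comparable to `N`, never
  selected by validation) are left at solver precision, where coordinate
  descent converges too slowly to be worth the cost.

Standardization statistics (per-SNP mean and SD) are computed on the
training rows and frozen for validation and test scoring; stored predictors
carry dosage-scale weights so they can score any target cohort.

**Hyperparameter selection** maximizes the validation metric (correlation
for continuous traits, AUC for binary) over the full `(l1_ratio, lambda)`
grid on a withheld validation set (default 2,500 samples; equal cases and
controls for binary traits). An optional one-standard-error rule steps back
to the sparsest solution within one bootstrap SE of the maximum, trading a
little validation performance for fewer features.

**Training ladders** are nested: a single shuffle defines every rung, so
each training set contains the previous one and metric growth across rungs
is not confounded by resampling noise. Continuous traits use geometric
total-sample rungs; case-control traits use equal cases and controls at
geometrically increasing case counts, with a final rung that adds every
remaining control to the maximal case set (case count is the `N` axis for
case-control curves, since the balanced rungs show that cases, not
controls, drive the metric). Five-fold cross-validation wraps the whole
procedure; each fold re-runs the pre-filter, path fit and selection from
scratch.

## Evaluation

* **AUC** uses the Mann-Whitney U statistic with ties counted one half, and
  the Hanley-McNeil finite-sample standard error.
* **Correlation** (with the adjusted phenotype) carries the Fisher-z
  standard error mapped back to the correlation scale.
* **Inclusive odds ratio**: at each score percentile `q`,
  `OR(q) = (cases >= q / controls >= q) / (total cases / total controls)`;
  at the lowest percentile the inclusive set is everyone and the OR is 1
  exactly. Bins left with no cases or no controls are omitted rather than
  reported as 0 or infinity. The Katz log-scale SE provides the interval.
* **Sibling tests**: for case-control traits, the affected-sibling-pair
  selection rate is the fraction of one-case/one-control pairs in which
  the case has the higher PGS, recomputed with pairs restricted to score
  differences of at least 0, 1.5, 2 and 2.5 SDs (the SD of the PGS within
  the sibling cohort); for continuous traits, the rank-order selection rate
  conditions on phenotype differences of 0, 0.5, 1 and 1.5 SDs. Exact ties
  are dropped and counted; empty cutoffs are reported as undefined, never
  as a rate of 0.
* **Single SNP variance**: `SSV = sum_i 2 beta_i^2 f_i (1 - f_i)`
  approximates `var(PGS)` by dropping between-SNP covariances — accurate
  for sparse predictors over weakly correlated SNPs, and checked in the
  tests against the empirical score variance on independent-SNP
  simulations (within 5%).
* **Variance explained**: `var(PGS)/var(y_adj)`; the same after inverting
  the sex-specific z-scoring on the PGS alone, referenced to the raw
  phenotype; and `corr(PGS, y_adj)^2`, which under `P = G + E` estimates
  the heritability captured by the predictor.

Cross-validation pooling reports the fold mean with the fold spread
(`var/k`) and the mean squared finite-sample error combined in quadrature.
The finite-sample estimators above are standard textbook choices; they are
documented here because the package treats them as conventions, not
contributions.

## Sparsity and the phase transition

Four operational definitions of predictor sparsity are computed from a
trajectory of (training size, active-SNP count, metric): the count at
maximal training; the count at the maximal *balanced* training; the count
at the rung of maximal relative metric increase `(y[i+1]-y[i])/y[i]`; and
the count at the rung of maximal relative increase in the feature count
itself. The last two are flagged undefined on flat or non-increasing
trajectories.

`detect_phase_transition()` locates the training size of the sharpest
metric jump on a geometric ladder. The jump statistic is the increment
normalized by the trajectory's total span rather than the running-value
ratio: the running-value ratio diverges when the early-rung metric sits
near zero and changes its argmax under affine rescaling of the metric,
whereas the span-normalized statistic is affine-invariant (the package
treats AUC - 0.5 and correlation on the same footing). `N*` is reported as
the geometric midpoint of the bracketing rung interval, since the ladders
are geometric. A transition is declared only when some increment exceeds
twice the pooled standard error; the detector also flags the
characteristic non-monotone signature in the active-set size (the solver
first accumulates SNPs, sheds 30% or more of them, then the metric jumps).

Compressed-sensing theory puts the LASSO support-recovery threshold at
`N* ~ 2 s log p` for heritability 0.5, where `s` is the number of causal
SNPs and `p` the panel size. Simulation studies on biobank-scale panels
(`p` of order 10^5 to 10^6, `2 log p ~ 27`) report this as `N ~ 30 s`. At
the desk scale used by this package's experiments (`p = 2000`,
`2 log p ~ 15`), the same theory — and the package's measurements —
place the transition near `15 s`: with `s = 20`, detected `N*` values
bracket 300 rather than 600. The `30 s` constant is therefore *not* a
universal ratio; it carries the `log p` of the panel it was measured on.
`phase_transition_sim()` reports whatever the detector finds and leaves
the interpretation to this scaling.

A pooled log-log regression `log10(s) ~ log10(N)` across traits and
sparsity definitions summarizes the empirical sparsity-data scaling; all
points are weighted equally (the trajectories give no principled weights).

## Projection to larger biobanks

Metric-versus-size curves are fit by four bounded four-parameter families,
`g(x) = a + b u(c (x + d))` with `x = log10(N)` and `u` one of logistic,
inverse tangent, error function, or hyperbolic tangent. The log axis is a
deliberate choice: the ladders are geometric and the bounded families need
a compactified axis to represent slow saturation. Constraints encode the
physics: the metric stays within its bounds (`a - b >= 0.5`, `a + b <= 1`
for AUC; `0` and `1` for correlation), growth is increasing in training
size (`b, c > 0`) and happens at positive sample counts (`d <= 0`). The
constraints enter through a smooth reparameterization; weighted least
squares (weights `1/se^2`) is solved by BFGS from multiple deterministic
and random starts, followed by a feasibility-preserving
Levenberg-Marquardt polish with the analytic Jacobian, which recovers
noise-free generating parameters to `1e-5`. The tanh kernel is an exact
rescaling of the logistic kernel, so the agreement of their asymptotes
(to `1e-4`) is used as a cross-check against local minima.

The parameter covariance is the inverse Gauss-Newton Hessian of the
weighted residual sum of squares, symmetrized and projected onto the
positive-semidefinite cone (near-singular Hessians are ridge-stabilized
with the condition number logged). Monte-Carlo bands draw
`theta = theta_hat + L X` with `C = L L'` the Cholesky factor and `X`
standard normal (default 10,000 draws), reject draws that violate the
constraints (rejection preserves the joint law, unlike truncation; the
rejection rate is logged and above 90% is an error), and report per-size
central 68% and 95% quantile bands. Note one consequence of rejection:
when the point estimate sits *on* a constraint boundary — e.g. a left
asymptote exactly at AUC 0.5 — about half the draws are rejected and the
accepted draws are correlated by the censoring; the draw-correlation
diagnostics are only meaningful for interior fits.

The infinite-data asymptote is `a + b`; its interval comes from the
accepted draws (or the delta method, `var(a) + var(b) + 2 cov(a,b)`, when
no band is requested). Asymptotes are pooled across families by an
inverse-variance-weighted mean, but — because all families are fit to the
*same* curve — the pooled standard deviation is the weight-averaged family
standard deviation rather than the independent-replicate `1/sqrt(sum w)`:
same-data fits cannot reduce uncertainty the way independent replicates
would, and coverage simulations confirm the naive rule undercovers
(roughly 75% instead of 95%) while the dependence-aware rule holds nominal
coverage. Between-family dispersion is added in quadrature so disagreeing
families widen the pooled interval.

A planned biobank is projected by evaluating the band at its effective
training size — `prevalence x cohort size` cases for case-control traits
(the conservative assumption that recruitment tracks population
prevalence), the cohort size for continuous traits — with an explicit flag
when that size extrapolates beyond ten times the largest fitted `N`.

## Problem sizes, tolerances and determinism

The test suite and the acceptance script run at desk scale, chosen to keep
every check sharp but fast: simulation fixtures of a few hundred to a few
thousand samples; the phase-transition experiment at `p = 2000`,
`s = 20`, `h2 = 0.5`, an 11-rung geometric ladder over `N in [100, 1800]`
with 500 validation and 1000 test samples, repeated over 5 seeds; growth
fits on 11-rung synthetic curves with per-point SE 0.01 and 100 coverage
replicates. Convergence tolerances: `1e-9` (scaled) for the path solver
with `1e-10` KKT refinement; `1e-15` relative for growth-fit optimization.
Solver cross-checks are run against an independently written coordinate
descent; metric oracles against exhaustive pair counting. All randomness
descends from explicit seeds; identical seeds give bit-identical outputs.

What passing these tests shows — and what it does not: the pipeline's
statistics are correct under the simulator's assumptions (independent or
block-AR(1) SNPs, uniform MAF, additive architecture, Gaussian
environment). Real cohorts add LD structure, stratification, assortative
mating, genotyping artifacts and phenotype misclassification, none of
which the simulator emulates; measured performance on real data is
expected to differ, most visibly in cross-ancestry transport.

## Known limitations

* No summary-statistic (GWAS-based shrinkage) training; predictors are
  trained on individual-level data only.
* Binary-trait effect sizes are reported on the observed scale; no
  liability-scale transformation is applied.
* The simulator has no recombination map, mutation model or X chromosome;
  sibling LD within blocks is approximate.
* The inclusive odds ratio and sibling tests assume the score
  distribution's extremes are populated; with small cohorts the top
  percentile bins are routinely omitted.
* Phase-transition constants depend on the SNP panel size through
  `log p` (see above) and may shift further under strong LD.
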