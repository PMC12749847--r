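---
title: "Multi-trait GBLUP for multi-environment trials: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait GBLUP for multi-environment trials: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtgblup)
```

## Scope

`mtgblup` implements the full genomic-selection workflow for
multi-environment breeding trials: SNP quality control and genomic
relationship matrix (GRM) construction; mixed-model adjustment of
plot-level data from incomplete-block designs; single-trait GBLUP by REML;
multi-trait GBLUP by Gibbs sampling; and the CV2 cross-validation scheme
that compares the two on identical folds. A synthetic-data generator draws
every layer (genotypes, genetic values, trial records) from the same
generative model the solvers assume, which is what makes the pipeline
testable end to end without field data.

## The statistical models

### Design adjustment

Plot records from an alpha-lattice trial are adjusted per trait with

* within environment: `y = mu + Rep + Block:Rep + Gen + error`,
* across environments: `y = mu + Env + Rep:Env + Block:Rep:Env + Gen +
  Gen:Env + error`,

with genotype fixed and every other term random IID normal, fitted by REML
(`lme4`). The genotype least-squares means (BLUEs, random effects at zero)
become the adjusted phenotype; environments are location × year
combinations, and the across-year variant substitutes the year for the
environment term when a single location is analyzed over seasons. The
suite pins the estimates two ways: the BLUEs against a dense
generalized-least-squares oracle at the fitted variance components, and the
REML optimum against a dense grid over the variance ratios (no grid point
may beat the optimum by more than 1e-4 log-likelihood units on a
30-observation instance).

Lines with any missing column are dropped (`complete_case_filter()`)
before prediction, because the cross-validation bookkeeping assumes a
complete line × column response matrix.

### GRM and single-trait GBLUP

The GRM is `G = ZZ' / (trace(ZZ')/n)` with `Z` the column-centered dosage
matrix, after filtering SNPs to minor allele frequency strictly above 0.05
and missing fraction strictly below 0.15 and imputing remaining gaps with
the per-locus observed mean. The trace normalization makes `mean(diag(G))
= 1`, so the genetic variance is on the per-line scale. Centering makes
`G` invariant to swapping the reference and alternate allele at any locus,
and the construction is invariant to SNP order; both are tested.

Single-trait GBLUP (`fit_st_gblup()`) profiles the restricted likelihood
over `h2` in the eigenbasis of `G`: with `G = V D V'`, the rotated model
has diagonal covariance `h2 D + (1 - h2) I`, the intercept is estimated by
GLS and the total variance profiled analytically, leaving a 1-D Brent
search on `h2` in `[1e-5, 1 - 1e-5]` (optima at the ends are flagged as
boundary estimates). Internally `G` is re-normalized to trace `n`, so
`h2`, BLUPs and predictions are invariant to the scale of the supplied
kernel while the reported `sigma2_u` refers to the caller's scale.

### Multi-trait GBLUP

q response columns are modeled jointly with `u ~ MVN(0, K (x) G)` and
`e ~ MVN(0, R (x) I)`. Two solvers share this model:

* `mt_blup_given_vc()` solves Henderson's mixed-model equations at fixed
  `(K, R)` over the observed cells; it is checked to 1e-8 against a dense
  oracle built literally from the Kronecker joint covariance, and reduces
  exactly to per-column single-trait prediction when `K` and `R` are
  diagonal.
* `fit_mt_gblup()` is the Bayesian fit: a Gibbs sampler (RcppArmadillo)
  cycling through (i) data augmentation of unobserved cells from their
  conditional normal given the line's observed traits, (ii) genetic values
  row-by-row in the eigenbasis of `G` (the full conditional precision of
  eigen-row i is `K^{-1}/d_i + R^{-1}`), (iii) inverse-Wishart draws of
  `K` and `R`, and (iv) intercepts. Because masked cells are augmented
  every iteration, their posterior means are the cross-validation
  predictions — no separate prediction step exists.

One intercept is fitted per column (rather than a single global mean)
because trait–environment columns sit on different scales; with a single
column the sampler collapses to the univariate model and its posterior
mean heritability agrees with the REML estimate (tested to 0.05).

### Heritability and reporting

Line-basis heritability is the diagonal of the elementwise ratio
`K / (K + R)`; genetic correlations are `K` scaled by the geometric mean
of its diagonal. `build_summary_matrix()` assembles the publication-style
three-zone display — heritabilities on the diagonal, correlations below,
covariances above, each with its posterior SD.

## The CV2 scheme

`make_cv2_partitions()` implements pair-balanced masking: each sampled
line is assigned to one unordered pair of columns and masked in both, all
`choose(q, 2)` pairs carry the same number `m` of lines, and sampling
continues until about 30% of lines are masked within each column. The
per-pair count is

```
m = floor(ceil(frac * n) / (q - 1)),
```

which is a reconstruction rather than a stated formula: it is the unique
simple rounding rule that reproduces all four published fold sizes
(per-column testing counts 66, 72, 70 and 74 for the n = 225/q = 4,
n = 244/q = 4, n = 245/q = 6 and n = 245/q = 2 configurations) from the
line and column counts alone; plain flooring or rounding of
`frac * n / (q - 1)` does not. With `q = 2` there is a single pair and a
sampled line is masked in **both** columns, so the multi-trait model has no
same-line auxiliary phenotype to borrow — the configuration in which
published gains nearly vanish, and the contrast the acceptance suite
reproduces qualitatively.

Both models are evaluated on the identical masks; `Pr` uses strict
inequality, so ties count against the multi-trait model. Undefined
correlations (a column with fewer than three masked cells, or zero
variance) are recorded as missing and excluded from averages with a count,
never imputed as zero.

## Synthetic world: what it emulates, what it does not

Defaults mirror the motivating study's dimensions: 245 lines, 12,000 SNPs
with allele frequencies uniform on [0.05, 0.5], two environments with two
replications of 21 incomplete blocks, two trait columns ("Fe", "Zn") with
heritability 0.6 and genetic correlation 0.9 on a unit phenotypic scale,
and 5% missing genotype calls. Choices the source material leaves open
were fixed once:

* Design-effect variances (environment 1.0, replicate 0.25, block 0.25 on
  the unit-phenotypic-variance scale) are free parameters with
  field-plausible defaults — large environment differences, smaller
  replicate and block effects.
* Genotype-by-environment deviations default to zero and, when enabled,
  are IID normal per (line, environment, trait).
* Design effects are drawn independently per trait; residual rows come
  from `MVN(0, R_true)` so residual trait correlations are respected.

The generator deliberately does **not** simulate linkage disequilibrium
(SNPs are independent), pedigree structure, population stratification, or
a resolvable alpha design (incomplete blocks are a re-randomized partition
per replicate; only the variance structure matters to the adjustment
model). A green test therefore establishes correctness of the estimation
machinery under the assumed generative model, not robustness to LD
patterns, kinship structure or spatial field trends in real data — and the
published real-data accuracy values themselves are reproducible only with
the archived phenotypes, which the package does not ship.

## Numerical choices

* Matrix square roots and `G^{-1}` use eigendecompositions; eigenvalues
  below `-1e-8` (relative) raise an error, smaller negative values are
  clipped to zero, and inversions floor the spectrum at `1e-8` of the
  largest eigenvalue — the centered GRM is always singular along the
  all-ones direction, and the floor is an infinitesimal ridge there.
* Covariance draws are symmetrized as `(A + A')/2` before decomposition.
* Inverse-Wishart priors use `nu = q + 4` degrees of freedom with the
  scale set so the prior mean of each of `K` and `R` is half the observed
  phenotypic covariance — proper and weakly informative, mirroring the
  common variance-partition heuristic of standard Bayesian GBLUP software;
  both knobs are exposed in `mt_chain()`.
* Default chain: 12,000 iterations, 2,000 burn-in, thinning 5. Cross-
  validation fits default to much shorter chains (1,500/500/2): posterior
  *means of predictions* stabilize far faster than covariance posteriors,
  and each partition is an independent chain. Chains are deterministic
  given their seed (R's RNG drives the compiled sampler).
* REML variance iterates are constrained to the `[0, inf)` boundary by
  `lme4`; `fit_st_gblup()` reports boundary optima explicitly.
* One-level grouping factors (e.g. a single replicate) are dropped from
  the adjustment formula rather than fitted, and their variance reported
  as zero.

## Design decisions that were genuinely open

* **MAF on observed calls only.** Whether allele frequencies were computed
  before or after imputation is not stated in the source material; the
  package computes them on observed entries and filters before imputing,
  so imputation (which preserves the observed mean) cannot move a SNP
  across the threshold.
* **Strict thresholds.** "MAF > 0.05" and "missing < 0.15" are taken
  literally: a SNP exactly at either boundary is dropped, and the suite
  pins this.
* **Pair masking for q = 2.** Whether a two-column testing set keeps the
  auxiliary column observed is ambiguous in the source description; the
  pair rule masks both, which is consistent with the near-zero published
  gains in that configuration, and the acceptance suite verifies the
  qualitative collapse of the gain rather than a specific magnitude.
* **Intercepts per column** in the multi-trait model (see above).
* **Seed layout.** One master seed; stage seeds are fixed offsets of it
  and CV2 draws one child seed per partition, so any partition or stage
  can be reproduced in isolation.

## Known limitations

* The adjustment models assume IID residuals; no spatial (row-column,
  AR1) correction and no per-environment residual variances.
* Only the trace-normalized linear GRM kernel is provided; no pedigree,
  Gaussian, or marker-effect (Bayes alphabet) models.
* The Gibbs sampler reports posterior summaries, not full chains; rerun
  with a different seed to assess Monte-Carlo error externally.
* CV1 (whole-line holdout) and leave-one-environment-out schemes are out
  of scope; CV2 is the scheme of interest here.
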