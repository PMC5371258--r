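---
title: "Genomic heritability, GBLUP and SNP-set contributions: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic heritability, GBLUP and SNP-set contributions: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partherit)
```

This vignette is the package's account of its statistical machinery: the
models, the tunable parameters and their defaults, what the simulator does
and does not emulate, the numerical choices, and the known limits of what
the tests demonstrate.

## The mixed model and its variance components

The analysis population is a set of n genotyped, phenotyped individuals
with one record each.  The phenotype model is

$$\mathbf{y} = \mathbf{X}_b\mathbf{b} + \mathbf{a} + \mathbf{d} + \mathbf{e},
\qquad
\mathrm{Var}(\mathbf{y}) = \mathbf{A}_g\sigma^2_\alpha +
\mathbf{D}_g\sigma^2_\delta + \mathbf{I}\sigma^2_e,$$

with fixed effects (intercept, batch factor with first level dropped,
optional covariates, optional SNPs fitted as fixed allele-count columns)
and two genomic random terms.  $\mathbf{A}_g$ is the VanRaden additive
relationship matrix; $\mathbf{D}_g$ uses the dominance-deviation coding
$(-2q_k^2,\,2p_kq_k,\,-2p_k^2)$ for codes $(2, 1, 0)$, normalized by
$\sum_k (2p_kq_k)^2$.  Allele frequencies always come from the analysis
sample after QC; both matrices are invariant to which allele is counted at
each SNP (a tested property).  Heritabilities are ratios to
$\sigma^2_y = \sigma^2_\alpha + \sigma^2_\delta + \sigma^2_e$ — the
model-implied phenotypic variance, not the raw sample variance of y — and
broad-sense heritability is the sum $h^2_t = h^2_\alpha + h^2_\delta$.

Estimation is average-information REML.  Each iteration computes
$\mathbf{P} = \mathbf{V}^{-1} - \mathbf{V}^{-1}\mathbf{X}
(\mathbf{X}'\mathbf{V}^{-1}\mathbf{X})^{-1}\mathbf{X}'\mathbf{V}^{-1}$,
the score vector and the AI matrix.  Numerical policy:

* a component pushed negative by an AI step decays geometrically toward a
  lower boundary of $10^{-6}\sigma^2_y$ instead (the rest of the step is
  kept: shrinking the whole step stalls when one component heads to zero);
* if the AI matrix is not invertible the EM update is used for that
  iteration;
* convergence is declared when the largest relative component change falls
  below `tol` (default 1e-8); boundary components are flagged;
* standard errors come from the inverse AI matrix; heritability standard
  errors by the delta method.

A direct evaluation of the restricted likelihood (`remlLogLik`) exists
solely so that tests can verify the maximizer against a grid search.

## GBLUP, reliability and back-solved SNP effects

GBLUP solves for all individuals using training phenotypes only; masked
(validation) individuals are predicted through their genomic relationships
to the training set.  Reliability of an individual's prediction is
$1 - \mathrm{PEV}_i / (K_{ii}\sigma^2_j)$ with the prediction-error
variance taken from the same projection matrix, and for the total genetic
value the kernel is $\mathbf{A}_g\sigma^2_\alpha +
\mathbf{D}_g\sigma^2_\delta$.  The dense Henderson mixed-model equations
are implemented independently inside a test as the oracle for these
solutions.

Per-SNP effects are back-solved as
$\hat\alpha = \mathbf{W}_a'\mathbf{A}_g^{-1}\hat{\mathbf{a}} / \sum_k
2p_kq_k$, which reproduces $\hat{\mathbf{a}} = \mathbf{W}_a\hat\alpha$
exactly (also when a pseudo-inverse replaces a singular
$\mathbf{A}_g$, because $\hat{\mathbf{a}}$ lies in its range).  The
per-SNP heritability is defined as the *partition* of the estimated
additive heritability proportional to each SNP's contribution variance,

$$\hat h^2_{k\alpha} = \hat h^2_\alpha\,
\frac{\mathrm{Var}_i(w_{ik}\hat\alpha_k)}{\sum_j \mathrm{Var}_i(w_{ij}\hat\alpha_j)}.$$

A design note: normalizing by the raw phenotypic variance instead would
make the values sum to $\mathrm{Var}(\mathbf{W}\hat\alpha)/\sigma^2_y$,
which is deflated by the BLUP shrinkage factor and cannot reproduce the
observed behavior that the per-SNP values sum to the total additive
heritability and that halving the panel almost exactly doubles the
per-SNP average while leaving the total unchanged.  The partition form has
both properties by construction (the halving ratio equals
$2\,\hat h^2_{half}/\hat h^2_{full}$), scales as $1/m$, and is what the
structural tests assert.

## GWAS scans

Three single-SNP methods:

* **GLS family scan** — $y = X_b b + Xg + Zf + e$ with a common family
  variance for sibs in the same family ("family" defaults to the litter,
  i.e. full sibs; a sire-family grouping is a flag away).  $\sigma^2_f$ and
  $\sigma^2_e$ are estimated once by REML under the no-SNP model (kernel
  $ZZ'$) and held fixed across SNPs: re-estimating per SNP would cost
  panel-size-fold more and changes single-SNP statistics negligibly.  Each
  SNP enters as a 3-level genotype factor; the additive contrast
  $(\mu_{22}-\mu_{00})/2$ and dominance contrast
  $\mu_{12}-(\mu_{22}+\mu_{00})/2$ are tested by t with
  $df = n - \mathrm{rank}$ (fixed design including the genotype columns).
  GLS is implemented by whitening with the Cholesky factor of V and
  re-estimating the residual scale, so it reduces *exactly* to OLS when
  $\sigma^2_f = 0$ (tested).  A genotype class below `minClass` (default 5)
  drops the factor fit for that SNP in favor of the allele-count
  regression, flagged in the output.
* **LS + MDS, additive** — allele-count regression with the leading
  classical-MDS coordinates of the 1 − IBS distance matrix as covariates
  (default 35 dimensions, the point where the inflation factor stabilizes
  in the motivating data).  Dominance is not estimable under this coding,
  so only additive tests are reported.
* **LS + MDS, genotypic** — the same covariates with the 3-level factor
  coding, testing both contrasts.

The genomic inflation factor is $\lambda =
\mathrm{median}(t^2)/0.4549364$.  The multiple-testing threshold is
Bonferroni $\alpha/m$; for a 41,108-SNP panel at $\alpha = 0.05$ this is
$10^{-5.91}$.  Manhattan-style output is tabular (chr, pos, $-\log_{10}p$);
plotting is left to downstream tools.

## Cross-validation and the three accuracy measures

`makeFolds(n, k)` partitions individuals at random into k folds of
$\lfloor n/k\rfloor$ with the remainder in the last fold — for n = 2936 and
k = 10 that is nine folds of 293 and one of 299.  Variance components are
re-estimated within each training fold (the alternative — reusing
full-data components — leaks information from the validation fold).  Per
fold and component j the package reports observed phenotypic accuracy
$\hat R_{0jp} = \mathrm{corr}(\hat g_{0j}, y_0)$ (raw phenotypes by
default; a fixed-effect-adjusted option exists), expected genetic accuracy
$R_{0j}$ = mean $\sqrt{\mathrm{reliability}}$ over the fold, and expected
phenotypic accuracy $R_{0jp} = R_{0j}\sqrt{h^2_j}$, pooled as mean ± SD
across folds.  $R_{0jp} \le R_{0j}$ always (the heritability factor);
$\hat R_{0jp}$ carries no such guarantee.

## SNP-set contributions: Methods I, II, III

For a named SNP set (ids or a `chr:start-end` region):

* **Method I** sums per-SNP heritabilities.  Because per-SNP heritability
  scales as ~1/m, the sum depends on the panel and is flagged accordingly;
  it exists mainly to demonstrate that dependence.
* **Method II** rebuilds the GRMs without the set and refits (optionally
  re-running CV).  SNPs in LD with the removed set absorb part of its
  signal, so the contribution is a lower bound.
* **Method III** keeps the full GRMs and fits the set as fixed allele-count
  covariates (2-df genotypic coding by option), removing their genotypic
  values from the phenotype; this also removes what their LD partners
  share with them, an upper bound.  Contributions are
  $c = 1 - \mathrm{reduced}/\mathrm{full}$ per heritability component and
  accuracy flavor.  When CV is involved, fixed SNP effects are estimated
  within each training fold and applied to validation individuals through
  their genotypes.

Fitting *every* panel SNP as fixed effects is refused before any numerics
(rank). `partialHeritabilityStability` recomputes Method III while the
panel is subsampled (the set always retained) to show that partial
heritability, unlike Method I, is insensitive to m.

## The simulator: what it emulates, and what it does not

`simConfig()` defaults are the study conditions of a commercial Duroc
nucleus population: 79 sires, 1456 litters (one unique dam each — the
source material does not describe dam reuse, so the simplest structure is
assumed), litter sizes 1–3, 41,108 SNPs on 18 autosomes, founder MAF in
(0.05, 0.5], narrow-sense heritability 0.365, dominance heritability
0.035, 24 year-month batch levels, and a discretized phenotype with mean
10.72 and SD 1.72.  Values the source does not state were fixed once at
field-realistic levels: adjacent-marker founder correlation `ldDecay` 0.7
(GBS-density local LD), 200 QTL (a moderately polygenic count trait),
batch SD 0.25 phenotypic SDs, and a recombination rate of one expected
crossover per chromosome (~1 Morgan).

Mechanics: founder haplotypes follow a first-order Markov chain over
markers (correlation `ldDecay`, restarting at chromosome boundaries) —
the simplest LD model that makes SNPs tag each other, which is the
behavior the removal/fixed-adjustment comparison hinges on.  Conditional
transmission probabilities are clamped to [0, 1], so realized LD is
somewhat below nominal when adjacent frequencies differ strongly.
Offspring receive one recombinant gamete per parent.  True breeding values
are $\sum_k w_{ik}\alpha_k$ over QTL; dominance deviations use the
orthogonal coding at the QTL's sample frequency so that simulated
dominance variance matches the model's definition.  Additive, dominance
and residual parts are rescaled on *realized* sample variances (not
expectations), so small-sample recovery tests are exactly calibrated;
batch effects are drawn once per level and centered; discretization rounds
to integers with the continuous SD reduced by the rounding variance 1/12
so the integer trait hits the target SD.

Not emulated: genotyping error and missingness (genotypes are complete),
sequence-level read simulation, selection, non-equilibrium demography,
dam reuse across litters, and multilocus LD beyond the first-order chain.
Passing tests therefore show correctness of the estimators under a
well-specified additive+dominance architecture with local LD — not
robustness to model misspecification on real data.

## Problem sizes in the test suite

The heavy checks run at deliberately chosen scales: parameter recovery at
~2000 individuals × 2000 SNPs × 200 QTL over ten seeds; null calibration
of the GLS scan over 2000 SNPs in 200 families; the panel-halving and
partial-heritability-stability properties at 1000–1700 individuals and
1000–1500 markers.  The halving property is asserted in the regime it
describes — markers redundant relative to the LD-block length
(`ldDecay` 0.95, causal variants excluded from the genotyped panel) — since
with sparse tagging the captured heritability itself drops when the panel
is halved and the ratio is no longer ~2.

## Known limitations

* Dense matrix algebra throughout: memory is O(n²) and REML time O(n³)
  per iteration; comfortable to a few thousand individuals, not hundreds
  of thousands.
* The dominance variance of a ~0.035 trait is frequently estimated at the
  boundary (zero) for n below ~1000; this is a property of the likelihood,
  not a defect, but means single-dataset dominance estimates at small n
  are mostly uninformative.
* The exact HWE test is a mid-p conditional test offered as an option; the
  chi-square is the default used by the filter thresholds.
* X-chromosome handling, imputation beyond per-SNP mean fill, haplotype
  block finding and multi-SNP (conditional/joint) association are out of
  scope.
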