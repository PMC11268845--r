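---
title: "Phenomic and genomic prediction for hybrid breeding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenomic and genomic prediction for hybrid breeding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenopred)
```

## The problem

Early-stage selection in hybrid rapeseed breeding must rank hundreds of
test hybrids before multi-year yield data exist. Genomic selection (GS)
predicts hybrid performance from genome-wide SNP markers through models
trained on phenotyped relatives. Phenomic selection (PS) applies the same
statistical machinery but replaces the marker matrix with near-infrared
(NIR) reflectance spectra of harvested seed — a cheap, routine
measurement that integrates genetic and physiological information about
seed composition. `phenopred` implements the full comparison pipeline
for a structured test-hybrid population: a synthetic-data generator with
the population and trial structure the analysis assumes, mixed-model
adjustment of traits and spectra, spectral preprocessing, SNP- and
NIRS-based relationship matrices, five prediction models, and
cross-validated prediction- and selection-accuracy evaluation.

No real genotype, trial or spectral data ship with the package; every
analysis stage is exercised and validated on simulated populations whose
generating process is under the user's control.

## The population the generator emulates

The simulated breeding material mirrors a commercial test-hybrid design:

* 5 founder lines are each crossed to one common elite line; from every
  cross a subfamily of fully inbred (doubled-haploid-like) pollinators is
  derived, 251 pollinators in total (subfamilies of 45–53 by default).
* Two male-sterile inbred testers serve as seed parents. 159 pollinators
  are crossed to both testers and 46 + 46 to one tester each, giving 410
  F1 test hybrids. Hybrid genotypes are deterministic given the inbred
  parents: dosage = (pollinator + tester)/2.
* Recombination in the pollinator genomes is modelled as inheritance of
  contiguous marker blocks (default 20) on one abstract linear genome.
  There is no genetic map; the blocks provide linkage structure for
  kinship contrasts, nothing more.
* Field trials are partially replicated (p-rep): per environment, 20% of
  entries are duplicated (1.2 replicates) and 3 check varieties appear 10
  times each. Plot values add environment, year, location,
  row-within-environment, column-within-environment,
  genotype-by-environment and residual effects to the genotypic value.
* Seed NIR spectra are simulated per plot in 2 technical replicates as a
  fixed smooth baseline + a low-rank genotype signal (random projections
  of the dosage matrix loaded onto smooth Gaussian-bump wavelength
  profiles, rank 10 by default, reproducing the strong inter-wavelength
  correlation of real NIRS) + an optional component proportional to the
  standardised genotypic value of the first trait (seed composition is
  genuinely trait-linked in real data) + a per-environment smooth effect
  + a per-scan baseline drift increasing with wavelength + white noise.

### What the generator does and does not capture

The generator reproduces the *statistical shapes* the pipeline relies on:
family structure, tester structure, p-rep unbalancedness, G×E, smooth
correlated spectra with baseline artefacts, technical replication. It
does not simulate sequence-level genetics (no map distances, no
selection or drift), non-additive trait architecture beyond what the
user injects, heteroscedastic or spatially correlated field errors, or
the chemistry that makes particular NIR bands informative. Passing tests
on this generator therefore demonstrate that the estimators and models
are implemented correctly and behave as theory predicts under their own
assumptions — not that phenomic selection will attain any particular
accuracy on real rapeseed data.

### Heritability convention and variance-exact draws

Trait heritability targets are defined on the entry-mean (Cullis) scale
of the configured design: with $J$ environments and $\bar r = 1 +$
`replicate_fraction` plots per genotype and environment, the genetic
variance is solved from
$h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{g\times e}/J +
\sigma^2_\varepsilon/(J\bar r))$,
so the generative target is directly comparable to the Cullis estimate
computed downstream.

All random-effect vectors drawn by the trial generator (environment,
year, location, row, column, G×E, residual) are *variance-exact*: each
vector is standardised so its realised sample variance equals its
configured component, exactly as the genotypic values are scaled to the
target genetic variance. For factors with few levels (5 environments)
the raw sampling noise of the draws would otherwise dominate any
parameter-recovery experiment — the median relative error of a variance
estimated from 5 unstandardised draws is ~16–40% before the estimator
contributes anything. With variance-exact draws, recovery experiments
measure estimator error, which is what they are for.

## Entry-mean adjustment

Traits and every spectral wavelength are adjusted to best linear
unbiased estimates (BLUEs) per genotype with the linear mixed model

$$y = \mu + g_i + e_j + r_{k(e_j)} + c_{l(e_j)} + a_m + l_n +
(g_i \times e_j) + \varepsilon,$$

genotype fixed, all design terms random with independent effects, fitted
by REML. The adjusted value per genotype is $\mu + g_i$. Check varieties
enter the fit (they stabilise the field-effect estimates) and are
dropped from the output. For spectra from a single location, and for
parental spectra, the reduced model omits environment, location and G×E
and nests rows and columns within year.

Implementation notes:

* Identity-covariance terms are fitted with lme4's sparse REML machinery
  behind the package's `reml_fit()` interface; terms with a covariance
  (kinship) matrix use the package's dense profile-REML optimiser
  (variance ratios on the log scale, `optim`, analytic profiling of the
  residual variance). On balanced one-way layouts the estimates equal
  the ANOVA estimators to at least six decimals (tested).
* Terms that are inestimable in a given layout — fewer than two levels,
  or one level per observation (confounded with the residual) — are
  dropped automatically; a fully saturated genotype model falls back to
  ordinary least squares, so single-environment unreplicated spectra
  pass through unchanged (up to nothing at all: the model is then the
  identity).
* Per-wavelength fitting refits the same factorised model structure via
  `lme4::refit`, re-estimating variance components at every wavelength
  (the default). A `"shared"` mode estimates components on 50 evenly
  spaced wavelengths, averages them, and solves Henderson's mixed-model
  equations for all wavelengths in one sparse multi-right-hand-side
  solve; it is an order of magnitude faster and agrees with the default
  to correlation > 0.98 in tests.
* Heritability is the Cullis form
  $H^2 = \sigma^2_g / (\sigma^2_g + \bar v_{\Delta BLUE}/2)$ with
  $\sigma^2_g$ from the genotype-random refit and $\bar v_{\Delta BLUE}$
  the mean variance of a pairwise difference of adjusted means, computed
  exactly from the fixed-effect covariance matrix for up to 1,000
  genotypes (10,000 sampled pairs beyond that).

## Spectral preprocessing

Technical replicates are averaged per plot, the adjusted genotype-level
profiles are differentiated with a Savitzky–Golay first derivative
(window 37 points, local polynomial order 2 — the lowest order that
admits a smoothed first derivative; the order is configurable), and the
derivative spectra are centred and scaled per wavelength to give the
predictor matrix $W$. The derivative removes additive baseline shifts
exactly (tested), and is exact for polynomial profiles up to the fit
order. Edges are trimmed, not padded: (window−1)/2 = 18 points per side,
so a 1,820-point profile yields 1,784 derivative points. Constant
columns cannot be scaled and are dropped with a warning.

## Relationship matrices and kernels

* Marker QC removes markers with >10% missing calls, non-biallelic
  dosages, or expected heterozygosity $2p(1-p) < 0.095$ (boundary
  inclusive), then mean-imputes remaining missing calls. Positional
  (reference-genome) filtering is out of scope.
* The additive genomic relationship matrix is VanRaden's
  $G_a = ZZ'/(2\sum_i p_i(1-p_i))$ with $Z$ the allele-frequency-centred
  dosages. Frequencies default to the supplied panel — typically the
  union of training and test individuals, so one matrix serves every
  cross-validation split.
* The spectral analogue is $G_{NIRS} = WW'/l$. For centred/scaled $W$,
  $\mathrm{tr}(G_{NIRS}) = n-1$, a useful invariant the tests exploit.
* RKHS kernels are Gaussian, $K_h = \exp(-h\,D^2_{norm})$, over the
  bandwidth grid {0.1, 0.5, 2.5}. Squared Euclidean distances are
  normalised by their mean off-diagonal value before the bandwidth is
  applied; without this the fixed bandwidth grid would be meaningless
  for feature spaces of a few thousand columns. The normalisation is
  switchable.
* `ensure_psd()` repairs round-off negative eigenvalues with escalating
  diagonal jitter and records what it added.

## Prediction models

All five models share one contract: train on the adjusted means of the
training individuals, predict every requested individual, with an
intercept plus a one-hot tester indicator as fixed effects.

* **GBLUP / NIRS-BLUP / combined** —
  $y = X\beta + Z_a a + Z_{NIRS} i + e$ with
  $a \sim N(0, G_a\sigma^2_a)$, $i \sim N(0, G_{NIRS}\sigma^2_i)$.
  Variance components by dense REML; out-of-sample prediction through
  the kinship cross-block. With matching variance components the
  predictions coincide with marker-effect ridge regression (RR-BLUP) to
  machine precision — the classical identity, used as an oracle test.
* **Bayesian LASSO** — $y = X\beta + Ma + Wi + e$, flat priors on
  $\beta$, double-exponential priors on effect vectors via the
  scale-mixture-of-normals representation; each predictor block gets its
  own squared regularisation parameter with a Gamma(1.1, 1e-5)
  hyperprior (weakly informative; the block's $\sum\tau^2_j$ dominates
  the update), residual variance scaled-inverse-$\chi^2$ with 5 prior df
  scaled to half the response variance. Default chain 12,000 iterations,
  2,000 burn-in, thinning 5. The sampler is validated against a 1-D
  quadrature oracle, reproduces ridge solutions when run with a fixed
  Gaussian prior, and collapses to the fixed-effect fit under extreme
  shrinkage. The effect-update sweep is implemented in C++ (Rcpp) with
  R's RNG, so chains are seed-reproducible.
* **RKHS kernel averaging** — $y = X\beta + \sum_l u_l + e$ with one
  variance component per kernel (three bandwidths per predictor type;
  six in the combined model); sampling happens in each kernel's
  eigenbasis (null directions dropped at $10^{-8}$ relative tolerance).
  Scaled-inverse-$\chi^2$ priors with 5 df split an assumed $R^2 = 0.5$
  equally across kernels. Kernel averaging emerges from the estimated
  variance-component weights. Out-of-sample random effects use the
  kernel cross-block through the training-block pseudo-inverse.
* **Random forest / support vector regression** — ranger (500 trees)
  and kernlab eps-SVR (RBF kernel). Hyperparameters (mtry between 100
  and one third of the feature columns, min.node.size in [3,15]; C in
  (0, 2^10] on a log scale, epsilon in [0, 0.5]) are tuned by
  model-based optimisation: 12 maximin Latin-hypercube evaluations, then
  6 evaluations proposed by a Gaussian-process surrogate with expected
  improvement; the objective is out-of-bag MSE (RF) or 5-fold CV MSE
  (SVR). A pure random search with the same 18-evaluation budget is
  available as a fallback, since GP surrogate internals are not uniquely
  determined. C's degenerate lower bound 0 is implemented as $10^{-6}$;
  integer parameters are rounded.

## Cross-validation and selection accuracy

Random cross-validation draws 200 (configurable) 80/20 splits — training
size floor(0.8·n), matching 319/80 at the 399-hybrid reference size —
and reports the Pearson correlation between adjusted means and
predictions of the masked test set per run; accuracies are aggregated as
medians. ML hyperparameters are re-tuned inside every training split.
Familywise cross-validation holds out each subfamily once. Constant
prediction vectors yield `NA` accuracy (reported missing, never zero).

Selection accuracy compares the top-k sets (k = 80 and 40, roughly 20%
and 10% of the population) selected on observed and on predicted values,
the latter averaged over all cross-validation runs. The four categories
(correctly selected a, wrongly selected b, wrongly discarded c,
correctly discarded d) partition the population, and the Czekanowski
coefficient $CZ = 2a/(2a+b+c)$ summarises overlap. For fixed-size
selections b = c and hence $CZ = a/k$ — e.g. 28 of 80 correct gives
0.35 and 35 of 80 gives 0.44. Top-k ties are broken by lexicographic id
order so results cannot be platform-dependent.

## Scenarios

`run_pipeline()` wires the stages together for four scenarios:
within-generation (hybrid spectra, full adjustment model),
single-location (spectra of one location, reduced model),
familywise (within-generation data under leave-one-subfamily-out CV),
and across-generation (spectra simulated on the pollinators grown at a
single location, adjusted with the reduced model, linked to hybrids
through the pedigree). Every run writes its artefacts plus a provenance
record (seed, scenario, model terms, parameter echoes, package version).

## Numerical choices and degenerate inputs

* Dense REML: variance ratios bounded to $e^{\pm 25}$, Nelder–Mead (or
  Brent for one component), relative tolerance $10^{-8}$, max 200
  iterations; non-convergence warns rather than fails silently.
* Monomorphic markers are rejected by `vanraden_grm` (frequencies at 0
  or 1) and removed by the QC filter before they get there.
* Constant wavelength columns: returned as-is with a warning by
  `adjust_spectra`, dropped with a warning by `center_scale`.
* All samplers take explicit seeds and are bit-reproducible; the
  generator derives an independent, fixed stream per stage from the
  master seed, so any stage can be re-run in isolation.

## Problem sizes used in the shipped experiments

The package's own experiments run at reduced but structurally faithful
sizes chosen to keep a full check of the pipeline inexpensive on a
laptop: parameter recovery at the full reference design (410 genotypes,
5 environments, 20 seeds), oracle equivalences at 50 individuals × 200
markers, the spectra-determined-trait check at 180 hybrids × 90
wavelengths, and the family-robustness experiment at 70 hybrids × 60
wavelengths × 20 seeds with 8 random splits per seed. Chain lengths in
tests (1,500–20,000 iterations depending on the oracle) are set so the
Monte-Carlo error is well below the tolerance being asserted; production
defaults are 12,000/2,000/5.

## Known limitations

* Residuals are independent; no AR1×AR1 spatial models (out of scope).
* GBLUP is additive-only; no dominance or epistatic relationship
  matrices (the RKHS kernels are the nonparametric route to epistasis).
* The Bayesian hyperprior constants are documented choices, not
  reproductions of any particular software's defaults.
* The generator's traits are mutually independent given the design;
  genetically correlated trait suites are not modelled.
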