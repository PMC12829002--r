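---
title: "Spatial GBLUP for smallholder dairy data: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial GBLUP for smallholder dairy data: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genetic evaluation separates what an animal transmits to its offspring (the
breeding value) from what its environment contributed to the measured
phenotype. The standard device for the environmental part is the contemporary
group — in dairy cattle, the herd. In smallholder systems this device breaks
down: herds hold one to nine cows, more than 70% hold a single cow, and herds
are genetically poorly connected. With a single cow per herd, the herd effect
and the cow's own merit are confounded; whatever the herd model cannot
capture leaks into the breeding values.

Nearby herds, however, share climate, soil, feed markets and management
culture. `spatialgblup` exploits that by adding a spatially correlated herd
location effect to genomic BLUP: herds close in space share environmental
information even when no herd has internal replication. The package provides
the four model variants, the machinery to compare them, and a synthetic-data
generator that emulates the smallholder data structure with known truth so
every claim can be checked against a ground truth.

## Models

For test-day milk yield `y_i` of cow `a(i)` in herd `h(i)`:

* **G**: `y_i = x_i'b + a_{a(i)} + e_i`
* **GH**: adds an independent herd effect `h_{h(i)}`
* **GS**: adds a spatial herd-location effect `s_{h(i)}` instead
* **GHS**: adds both
* a `P` in the label (e.g. `GPHS`) adds an iid permanent-environment effect
  per cow, accounting for the repeated records.

Distributions: `a ~ N(0, G sigma2_g)` with `G` the VanRaden type-1 genomic
relationship matrix; `h ~ N(0, I sigma2_h)`; `p ~ N(0, I sigma2_p)`;
`e ~ N(0, I sigma2_e)`; and `s ~ N(0, sigma2_s * R(rho))` where `R` is the
Matern (smoothness `nu = 1`) correlation over Euclidean distances between
herd coordinates in km. The range convention is `kappa = sqrt(8 nu)/rho`, so
`rho` is the distance at which correlation has decayed to about 0.1 (0.139
exactly for `nu = 1`). `nu = 1` is the standard 2-D Whittle choice and is
fixed; it is exposed as an argument only for completeness.

The fixed effects follow the standard test-day repeatability recipe:
intercept, four exotic-genome classes (C1: at least 87.5% exotic genome,
C2: [60, 87.5), C3: [36, 60), C4: below 36 — classes closed at their lower
bound), parity (1, 2, 3+), calving year-season (January–June is the dry
season), test year-month, a standardised age-at-calving slope nested in
parity, and unnormalised Legendre polynomials of order 2 in days-in-milk
nested in parity (the order-0 term is absorbed by the parity intercepts;
normalisation constants are absorbed by the coefficients, so coefficients
are not comparable across Legendre conventions). Categorical levels are
derived from the data, never hard-coded, and reference-coded against the
first sorted level; any full-rank coding gives the same fit, and the proper
prior keeps even rank-deficient designs well-posed.

## Inference

All effects and the genomic/herd/permanent/residual variances have Gaussian
or conjugate gamma full conditionals, so the sampler is Gibbs with two
embedded random-walk Metropolis–Hastings steps for parameters without
conjugate updates:

1. fixed effects, breeding values, herd, spatial and permanent effects are
   drawn blockwise from their Gaussian conditionals;
2. the spatial hyper-parameters are updated against the *marginal*
   likelihood with both herd-level effects (`h` and `s`) integrated out,
   once reallocating variance between `sigma2_h` and `sigma2_s` and once
   moving `(log rho, log sigma_s)`; `s` is then redrawn conditionally. The
   collapsing matters: in singleton-herd data `h + s` is well determined but
   the split is not, and conditioning the hyper-parameter moves on the
   current fields freezes the chain. All dense algebra stays at herd
   dimension via Woodbury/Sylvester identities, checked against direct dense
   evaluation in the tests;
3. variances are redrawn from their scaled inverse-gamma conditionals.

Priors follow common practice for this model class: `N(0, 1000)` on the
intercept and fixed effects; `Gamma(1, 5e-5)` on the precisions of the
genomic, herd, permanent and residual variances; and a penalised-complexity
(PC) prior on the spatial pair, exponential on `sigma_s` with
`P(sigma_s > 1) = 0.1` (the phenotype is standardised, so a spatial sd of 1
is a whole phenotypic sd) and the `rho^-2 exp(-lambda/rho)` PC form on the
range. The range reference is scale-aware: `P(rho < rho_0) = 0.05` with
`rho_0` the 5th percentile of the nonzero pairwise herd distances. We
deliberately do *not* anchor the range prior at the global median pairwise
distance: with herds clustered in a few regions, the median pairwise
distance is a between-region distance (hundreds of km), and anchoring there
puts essentially zero prior mass on any within-cluster range. Penalising
only ranges below the smallest resolved scale is the standard PC
recommendation and leaves the data free to choose. Both reference values
and both tail probabilities are arguments of `model_spec()`.

Step sizes of both MH moves adapt during burn-in towards a 20–40% acceptance
rate and are frozen afterwards. Defaults are 4,000 iterations, 1,000
burn-in, thinning 3, one chain; every fit records effective sample sizes for
the variance components and warns below 50. Per-record Gaussian
log-likelihoods are stored per retained draw, giving WAIC directly.

A deterministic companion, `mme_solve()`, solves Henderson's mixed-model
equations at fixed variance components (with the proper Gaussian prior on
the fixed effects as a ridge and a `1e-6` diagonal stabiliser on `G` applied
at solve time only). It serves three roles: an exact oracle for the sampler
(with all variances clamped, the posterior mean of every effect equals the
MME solution — an acceptance test asserts this within Monte-Carlo error); a
fast refitting engine for validation folds; and the kriging predictor, since
solving the joint system with unobserved herds included automatically gives
prior means of zero for unseen iid effects and the Matern conditional mean
at held-out locations.

## Model evaluation

* **WAIC** from the stored log-likelihood draws
  (`-2 (lppd - p_waic)`, lower is better).
* **Realised spatial variance**: the variance parameter `sigma2_s` describes
  the field over all space; the realised spatial variance is the variance of
  the field *at the observed herd locations*, computed per posterior draw
  and summarised (by default over 1,000 draws). With clustered herds the
  parameter is typically larger than the realised value, and only the
  realised value is comparable across models.
* **Contribution correlations**: per-record contributions of EBV, herd and
  spatial effects are merged across models and correlated (Pearson above,
  Spearman with midranks below the diagonal). A near-zero correlation
  between a spatial model's EBV contribution and the spatial contribution —
  against a large one for the non-spatial model — is the signature that the
  spatial term removed environmental signal from the breeding values.
* **EBV shift**: regressing per-animal `EBV_GH - EBV_GHS` on the estimated
  spatial effect at the animal's herd. A positive slope means the
  herd-only model overrates animals in good environments and underrates
  animals in poor ones.
* **Cross-validation** masks all records of one exotic-genome class (or one
  region) and predicts them from the rest, scored as the Pearson correlation
  between predicted and observed phenotype; **forward validation** masks all
  records of cows born at or after a cutoff year. Refits default to the
  mixed-model-equations engine at variance components estimated once per
  model on the complete data — the standard fast BLUP cross-validation;
  `method = "mcmc"` refits the full sampler per fold instead. Effect
  estimates driving the predictions are always trained on training records
  only. Both plain and record-weighted fold averages are reported, since the
  choice of average is a convention.

## The synthetic-data generator

The generator emulates the data structure the method is designed for, at a
desk scale of roughly one quarter of the motivating study:

* ~500 cows in ~355 herds (herd-size distribution over 1..9 with 71%
  singletons and >93% below 3 cows, matching the smallholder census shape);
* herds clustered hierarchically: 4 regions a few hundred km apart, 18
  wards per region (the study system has 72 wards), ward centres scattered
  50 km (sd) around region centres — regional clusters spanning one to two
  hundred km, as in the motivating geography — and herds 3 km (sd) around
  ward centres. The ward level is essential, not cosmetic: with herds
  scattered tens of km apart, a 30-km-range field is statistically
  indistinguishable from iid herd effects, which is not the geography these
  systems have. A consequence worth knowing: at this ward spacing the
  simulated field carries little between-ward correlation, so regional mean
  environments are mild; the strongly region-coherent fields of real data
  reflect multi-scale environment (altitude, climate) that a single
  short-range stationary field does not generate;
* region-correlated admixture: mean exotic proportion differs by cluster
  (0.82/0.65/0.72/0.85), emulating the documented pattern that some regions
  import far more exotic germplasm than others. This genetics-by-geography
  correlation is part of what makes separating genetic and environmental
  effects hard in these systems;
* admixed genotypes: each cow's exotic-genome proportion is Beta(2.6, 0.8)
  (chosen to match the published four-class composition of the motivating
  population: 39/41/16/4% for C1–C4), and each SNP dosage is Binomial(2, p)
  with p the admixture-weighted mix of exotic- and indigenous-pool
  frequencies (each Uniform(0.05, 0.95) per SNP). This produces the
  dominant admixture gradient in the genomic relationships but no linkage
  disequilibrium, pedigree or selection structure;
* breeding values from marker effects, `alpha ~ N(0, var_g / (2 sum
  p(1-p)))` on centred dosages, so the simulated architecture is exactly
  the GBLUP model and `var(a)` matches `var_g` under the VanRaden scaling
  without factorising a possibly semi-definite `G`;
* repeated test-day records, Poisson around 10 per cow (the study reports
  only the mean; Poisson is our choice, not a claim about the study), with
  roughly monthly DIM spacing inside [4, 500], parities pooled 1/2/3+,
  calving seasons derived from the calving month;
* default variance components `var_g = 0.15`, `var_h = 0.15`,
  `var_s = 0.3`, `var_p = 0`, `var_e = 0.3` (standardised-phenotype units)
  and `rho = 30 km` — magnitudes in the range reported for such data, with
  the spatial share deliberately large relative to the genomic share so
  spatial confounding is present by construction;
* `milk_yield` written in litres as `8.3 + 4.3 * y` (the field-typical
  test-day mean and sd), so the raw-data filters and standardisation of the
  loading module are exercised end to end.

What passing tests on these data do *not* show: robustness to linkage
disequilibrium and multi-breed haplotype structure, to non-Gaussian
environmental shocks, to genotype-by-environment interaction, or to
informative (non-random) geographic sampling. The generator's model matches
the fitted model by design; on real data none of these alignments hold
exactly.

## Numerical choices and degenerate inputs

* Matern correlations are set to 0 where `kappa d > 38` (true value below
  1e-14) and to 1 at exactly zero distance; duplicated herd locations are
  collapsed before field simulation so they receive identical values.
* Covariance matrices get a `1e-8` diagonal jitter before Cholesky (the PSD
  repair is logged when triggered at user level); `G` gets `1e-6` at solve
  time only and is stored unmodified.
* Residual missing dosages after QC are mean-imputed (`2p`); allele
  frequencies are always the observed sample frequencies.
* Standardisation uses the population sd (divide by n) and stores the
  statistics so held-out data are standardised with training statistics
  (no leakage).
* All range-type filters (yield 1–45 L, DIM 4–500, age at first calving
  at least 18 months) are inclusive at both ends.
* Zero-variance columns in correlation tables give NA with a warning; an
  all-zero EBV shift reports slope 0 and R² 0 by convention; accuracies are
  NA for folds with fewer than 3 records or constant predictions.
* `cut`-style class boundaries at 87.5/60/36% exotic genome are closed at
  the lower bound of the upper class, consistent with half-open interval
  notation for the published class table.

## Experiment sizes

The acceptance-level experiments simulate at the generator defaults (500
cows, ~355 herds) for parameter recovery and for the EBV-shift confounding
diagnostic — 20 replicates with 1,200 MCMC iterations (400 burn-in,
thinning 2) per fit — and at 150 cows with 800 iterations for the
model-comparison, decorrelation and validation-ordering experiments, 10
replicates each. The shift diagnostic regresses the difference between the
two models' deterministic BLUP breeding values (each at its model's
posterior-mean variance components) on the true field, so the regression is
not diluted by sampler noise. These are the package's chosen desk-scale
study conditions: large enough that the qualitative phenomena (WAIC
ordering, EBV shift along the field, decorrelation, validation ranking) are
reproducible, small enough to run routinely. One caveat is intrinsic rather
than computational: with herds in ~72 wards there are only ~70 effectively
independent field sites, so the posterior of `sigma2_s` conditions strongly
on the single realised field and its frequentist coverage is expected to
run slightly below nominal at this scale regardless of chain length.

One structural limitation deserves its own paragraph. The generator's only
source of genetic relatedness is the admixture gradient — pedigree and
family structure are deliberately out of scope. In real smallholder data,
relatives cluster spatially (local bulls, farmer networks), and that is the
channel through which a herd-only model's EBVs absorb regionally coherent
environment: a shared regional offset is cheap to express along a direction
of the relationship matrix when the region's animals are genetically
similar. With admixture-only relatedness that direction barely exists, the
free iid herd effect absorbs the field instead (its variance estimate
inflates towards the sum of herd and spatial variance), and the EBV
difference between the herd-only and the spatial model stays an order of
magnitude below what confounded real data show. The package's diagnostics
still demonstrate the contamination cleanly for the no-herd-effect baseline
(whose EBVs correlate strongly with the spatial contribution until the
field is modelled), but the herd-vs-spatial EBV shift should be expected to
be weak on data simulated here, and strong on data with genuine family
structure.

## Known limitations

* The exact dense Matern covariance is used throughout; cost grows with the
  cube of the number of herds, so a few thousand herds is the practical
  ceiling. Mesh/SPDE approximations used by large-scale spatial software
  are intentionally out of scope.
* One chain by default; multiple chains are supported (`chains` in
  `model_spec()`) and simply concatenate draws after per-chain burn-in.
* Permanent-environment variants are implemented but, as in the motivating
  literature, are poorly identified when most herds have one cow:
  genomic variance can transfer almost entirely into the permanent term.
* The lon/lat-to-km helper is an equirectangular approximation for toy use;
  real analyses should supply properly projected coordinates.
* Prediction intervals for phenotypes are not provided; the package reports
  posterior summaries of effects and point predictions for validation.
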