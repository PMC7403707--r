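---
title: "Vector-based analysis of plasticity and local adaptation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vector-based analysis of plasticity and local adaptation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastvec)
```

## The question and the design

When a population colonizes a novel environment, its first phenotypic
response is plastic. Whether those environmentally induced phenotypes
foreshadow the genetic changes of later local adaptation — plasticity
"taking the lead" — is a long-standing question in evolutionary biology.
Reciprocal transplant experiments give exactly the data needed to ask it
quantitatively: two populations (A, putatively ancestral; B, derived), each
grown in its own and in the other population's environment, yield four
experimental units — AinA, AinB, BinB, BinA — each an `n × d` matrix of
individuals by traits.

`plastvec` treats each comparison as a configuration of four multivariate
centroids and works with centroid-difference vectors:

* **plasticity of A**: AinA → AinB (the ancestral population's plastic
  response to the derived environment),
* **plasticity of B**: BinB → BinA,
* **total phenotypic difference**: AinA → BinB (each population at home),
* **evolutionary divergence**: AinB → BinB (both populations in environment
  B, so the difference is attributable to genetic change).

The effect sizes are the geometry of these vectors: the angle between the
two plasticity vectors (`angle_pp`; with the home→away orientation used
here, *similar* plastic responses appear **anti-parallel**, near 180°); the
angle between plasticity of A and the total difference (`angle_pt`; 0°
means plasticity points exactly at the locally adapted phenotype, 90° is
the random expectation); the angle between plasticity and evolutionary
divergence (`angle_pe`); the undirected angles between the leading
eigenvector of a unit's phenotypic covariance matrix (P-matrix, axis
"Pmax") and divergence or plasticity (`angle_pmax_e`, `angle_pmax_p`; 45°
is random because axes fold at 90°); the signed projection of plasticity
onto the total difference as a percentage (`projection_pct`; over 100% the
plastic response *overshoots* the locally adapted phenotype, negative means
*opposite*); the log length difference of the two plasticity vectors; and
log trace-ratios of foreign-vs-home P-matrices (`log_var_ratio_A/B`),
summarizing how total phenotypic variation changes in a foreign
environment.

A comparison is classified **opposite** when `angle_pt > 90°`,
**overshoot** when the projection exceeds 100%, otherwise **undershoot**;
an angle of exactly 90° (projection exactly 0) counts as undershoot — the
boundary case carries no evidence of opposition.

## Standardization

Raw traits mix units (millimetres, days, counts), on which angles are
meaningless. `standardize_traits()` z-scores each trait within a comparison
using the grand mean over all four units and the **pooled within-unit SD**
(`sqrt(sum_u SS_u / sum_u (n_u - 1))`). Scaling is common to the four
units, so between-unit mean shifts — the vectors themselves — are
preserved; a per-unit scaling would distort them. A trait with zero pooled
variance is an error, not a silent drop. Phenology traits are used as
recorded (e.g., days); no growing-degree-day conversion is attempted, which
is worth remembering when phenology-driven "opposite" classifications
appear.

Because standardization rescales each trait axis by its own pooled SD, it
is an anisotropic map unless the within-unit covariance has equal
diagonal: true angles defined on the raw scale are preserved exactly under
a spherical P-matrix and asymptotically whenever the diagonal is constant.
The synthetic-data paths that validate end-to-end angle recovery therefore
use spherical P-matrices; the generator's ground truth always refers to the
noiseless centroid configuration it constructed.

## Monte Carlo sampling variances

Each effect size is a nonlinear functional of four estimated centroids and
P-matrices, so no convenient closed-form sampling variance exists. The
package attaches one by **parametric bootstrap of individuals**: each
replicate redraws every unit's `n` individuals from
`MVN(centroid, P-matrix)` and recomputes all statistics
(`mc_effect_sizes()`). The Monte Carlo mean is the point estimate carried
into the meta-analysis (matching the per-comparison means displayed on
circular effect-size plots; the plug-in estimate is stored alongside, and
the difference is a small-sample bias correction for these bounded
statistics), and the Monte Carlo variance is the effect's sampling
variance. The bootstrap respects each unit's own sample size and remains
valid when `n - 1 < d`; a Wishart variant (`mechanism = "wishart"`), which
draws the replicate P directly from its Wishart distribution and the
replicate mean from `MVN(centroid, P/n)`, is asymptotically equivalent and
available as a switch. Angles are pooled on the linear degree scale — the
distributions are bounded at 0/180 rather than circular, so circular
statistics would be inappropriate.

Defaults: `n_reps = 10000` per comparison (tests and examples use a few
hundred, which is enough to exercise the machinery; production sampling
variances deserve the full default); per-comparison seeds derive
deterministically from a master seed plus a hash of the comparison id, so a
pipeline run is reproducible end to end and adding comparisons does not
shift the streams of existing ones. An effect whose statistic is undefined
on the observed data, or in more than 10% of replicates (vanishing
vectors), is an `unstable-effect` error rather than a number.

Effects computed from the same experimental units are not independent —
the shared-control-group problem. `build_sampling_covariance()` models the
covariance of sharing pairs as `r * sqrt(v_i v_j)` with a fixed `r = 0.5`
(the conventional choice when the true overlap correlation is unknown),
zero otherwise, and clips to the nearest PSD matrix (with a warning) in the
rare case the fixed-`r` construction is indefinite.

## Multilevel meta-analysis

Effect sizes are pooled with the standard multilevel meta-analytic model:

`y = X beta + Z u + e_obs + e_sampling`

with `u ~ N(0, tau2_study I)` over studies — or `N(0, tau2_phylo Phi)` over
species, `Phi` a phylogenetic correlation matrix — an observation-level
random effect `e_obs ~ N(0, tau2_obs I)` (residual heterogeneity among
comparisons within studies), and known sampling covariance `V` from the
Monte Carlo step. Estimation is REML through `metafor::rma.mv()`, the
standard engine for this model class; the package wraps it behind
`fit_random_effects()`, which returns a `plast_meta` object with
print/summary/coef/predict methods. The closed-form inverse-variance GLS
mean (with variance components fixed at zero) serves as an independent
correctness oracle in the test suite, as does the exact equivalence of the
study and phylogenetic structures when `Phi = I` with one species per
study.

`Phi` comes from a dated ultrametric tree: the correlation of two species
is their shared root-to-MRCA branch length over total tree depth
(`phylo_correlation_matrix()`, computed via `ape`); the tree must be
rooted, binary and ultrametric to tolerance `1e-6`, and is pruned to the
species at hand. Since study and species are typically confounded in
compiled transplant data, `compare_random_structures()` fits both
structures on identical data and ranks them by **AICc**,
`-2 logLik + 2p + 2p(p+1)/(k - p - 1)`, with `p` counted explicitly as
fixed effects plus *estimated* variance components (the count is a
documented choice; fixed components are excluded). Ties within 2 AICc
units resolve to the study structure, the conventional default. AICc at
`k <= p + 1` is `Inf` with a warning.

Confidence intervals are Wald (`beta ± 1.96 SE`), hence symmetric.
Published angle means sometimes carry asymmetric intervals, suggesting a
transform near the 0/180 boundaries; no specific transform is documented
for this model class, so none is guessed at here — a known limitation.

Meta-regression admits three main-effect moderators: the number of traits,
the proportion classified as morphology (vs phenology), and the strength
of local adaptation. The first two are z-scored before fitting, so slopes
are per-SD and `predict()` reports pooled means at the moderator mean and
±1 SD; interactions are deliberately out of scope at these sample sizes.

## Local adaptation

Inclusion requires demonstrated local adaptation: at least one fitness
measure higher in at least one native-vs-transplant contrast, assessed by
Hedges' g (`g = J (mean_native - mean_foreign) / s_pooled`,
`J = 1 - 3/(4(n1+n2) - 9)`) being positive for BinB vs AinB or AinA vs
BinA. The `local_adaptation_g` moderator is the B-environment contrast —
the derived population's home, where adaptation of interest happened. With
several fitness measures the one flagged primary in the input metadata
wins (else the first listed); measures are never averaged, since no
principled weighting across, say, survival and seed count exists.

## The synthetic-data generator

`generate_comparison()` builds a comparison from exact centroid
construction — `AinA = base`, `AinB = AinA + plasticity_A`,
`BinB = AinB + divergence`, `BinA = BinB + plasticity_B` — with individuals
drawn MVN around them under a P-matrix specified by eigenvalues and an
orientation (identity, random rotation, or explicit). `plasticity_B`
defaults to `"mirror"` (`-plasticity_A`): perfectly conserved plasticity,
true `angle_pp` of 180°, the empirically motivated reference point from
which users dial divergence of plastic responses. Fitness is normal with
unit SD; home units are offset by `g/J` so the expected Hedges' g equals
the target. Every implied statistic is recorded in closed form, and a
property test asserts the generator's truth equals the geometry module
applied to the noiseless centroids — a two-sided cross-validation of both
components.

`generate_meta_dataset()` emulates a compiled multi-study dataset: true
per-comparison effects follow `theta_ij = mu + u_i + w_ij` with
`u_i ~ N(0, tau2_study)`, `w_ij ~ N(0, tau2_obs)`. Defaults describe a
realistic compiled literature: 34 studies, mostly single-comparison (68%
of studies; range 1–15), trait counts `round(N(3.82, 1.91))` clamped to
2–9, roughly two-thirds of studies all-morphology / a tenth all-phenology
/ the rest mixed, one species per study (study and species confounded, as
in real compilations), related through a random coalescent tree rescaled
to depth 1. Two realization levels serve different validation needs:

* `level = "effect"` adds sampling noise `N(0, vi)` with `vi` drawn
  uniformly from 4–64 (sampling SDs of 2–8°, typical of the Monte Carlo
  step at transplant-study sample sizes) and returns a ready-to-fit
  dataset — the standard design for checking the meta-analytic layer in
  isolation (bias, CI coverage).
* `level = "individual"` realizes every comparison as a full 4-unit design
  whose true focal angle equals `theta_ij` (clamped to [1°, 179°]), with
  per-unit `n` uniform on 10–40, so the entire pipeline — file I/O,
  standardization, geometry, Monte Carlo, meta-fit — runs end to end on
  files it wrote itself.

What the generator does *not* emulate: skewed or zero-inflated trait
distributions, missing-data patterns, unequal per-unit sample sizes within
a comparison, heterogeneous P-matrices among units, or selective mortality
contaminating "plasticity". Passing tests demonstrate correctness of the
estimators under the declared model, not robustness to every failure mode
of real field data.

## Numerical choices

* Angles are computed in radians with the normalized dot product clipped
  to [-1, 1] and reported in degrees; near-(anti)parallel configurations
  are then safe, at the cost that an exactly-zero angle reconstructed
  through floating-point centroid subtraction can come out as ~1e-6
  degrees (the acos derivative is unbounded at the boundary).
* Eigendecompositions sort eigenvalues descending, clip small negative
  values to zero, sign-normalize each axis so its largest-magnitude
  loading is positive, and break exact eigenvalue ties by preferring the
  axis loading most on the first trait — deterministic output across
  platforms.
* Total phenotypic variation is summarized by the P-matrix trace
  (rotation-invariant); variance change is computed as a log trace-ratio
  for pooling and back-transformed to a percentage for reporting.
  Alternatives (determinant, mean variance) would answer slightly
  different questions; trace is the package's documented choice.
* REML uses `nlminb` with a documented restart under Nelder–Mead before a
  convergence error is raised.
* The shape-ratio correlation (`eigen_ratio_correlation()`) is Pearson by
  default with percentile CIs from joint parametric resampling of the
  P-matrices at their own sample sizes.
* The ancestral-order sensitivity analysis flips each ambiguous
  comparison independently with probability 1/2 per randomization
  (flipping exchanges the two plasticity vectors and negates the total
  difference, leaving `angle_pp` invariant — itself a tested property),
  caches results per flip pattern, and with a single ambiguous comparison
  reduces to exact enumeration of both assignments.

## Validation scales

The test suite checks analytic values on printed inputs, property-style
invariants on randomized cases under fixed seeds, and the statistical
guarantees at these problem sizes, chosen so the full suite runs in well
under a minute while Monte Carlo tolerances stay meaningful: calibration
of random directed/undirected angles at 100,000 pairs (±0.5°); pooled-mean
recovery over 100 synthetic meta-datasets of 40 studies (bias < 2°,
coverage within [88%, 99%]); sampling-variance monotonicity over per-unit
n of 10/50/250 at 1,000 replicates; end-to-end consistency at 10,000
individuals per unit (within 2° / 5 percentage points of truth).

## Limitations

Headline numbers from any real compiled dataset additionally depend on
curation decisions (study screening, trait selection, ancestral-order
assignments) that are inputs to, not outputs of, this package; users map
their compiled data onto the documented CSV schema with a thin adapter.
G-matrices are not estimated — P is the standard proxy, and the Pmax
statistics inherit that caveat.
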