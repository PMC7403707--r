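# plastvec

Vector-based meta-analysis of phenotypic plasticity and local adaptation
in reciprocal transplant experiments.

## The problem

Reciprocal transplant experiments grow two populations (A, putatively
ancestral; B, derived) in both environments, producing four experimental
units — AinA, AinB, BinB, BinA — each a matrix of individuals × traits.
Whether the ancestral population's plastic response to the derived
environment *anticipates* the phenotype of the locally adapted population
is a multivariate question: single traits can drift up or down freely, but
trait **combinations** are constrained by development. `plastvec` answers
it with vector geometry in standardized trait space, for anyone compiling
or analyzing transplant studies (evolutionary ecologists, meta-analysts).

Writing the unit centroids as `x̄(·)`, the package builds

- plasticity of A: `p_A = x̄(AinB) − x̄(AinA)` (and `p_B` analogously),
- total phenotypic difference: `t = x̄(BinB) − x̄(AinA)`,
- evolutionary divergence: `e = x̄(BinB) − x̄(AinB)`,

and derives the effect sizes: angles `∠(p_A, p_B)`, `∠(p_A, t)`,
`∠(p_A, e)` (degrees; 90° = random orientation, and with the home→away
convention, *similar* plasticity in the two populations shows up near
180°); undirected angles between a unit's leading P-matrix eigenvector
(`P_max`) and `e` or `p_A` (0–90°; 45° = random); the signed projection
`100 · (p_A · t̂)/‖t‖` classifying each comparison as
opposite / overshoot / undershoot; the log length difference
`ln‖p_B‖ − ln‖p_A‖`; and log trace-ratios of foreign- vs home-environment
P-matrices.

Because these statistics have no closed-form sampling variances, each gets
a Monte Carlo one — parametric bootstrap of individuals at the observed
centroid and P-matrix, respecting each unit's sample size. Effects are
pooled with a multilevel random-effects meta-analysis (REML via `metafor`)
with study-level or phylogenetic random structures compared by AICc, a
shared-unit sampling covariance (`r = 0.5`), and moderators including a
Hedges' g measure of local adaptation strength. A synthetic-data generator
with closed-form ground truth validates the whole chain.

## Worked example

```r
library(plastvec)

# one synthetic comparison: known plasticity and divergence vectors
gen <- generate_comparison(generator_spec(
  d_traits = 3, n_per_unit = 25,
  plasticity_A = c(1, 0.3, 0),
  divergence   = c(0.1, 0.3, 0.2),
  P_eigenvalues = rep(0.4, 3),
  fitness_g = 0.8, seed = 2024))

comp <- standardize_traits(gen$comparison)
comparison_geometry(comp)
#> <rt_geometry S1/C1>
#>   angle_pp 164.23  angle_pt 24.74  angle_pe 71.78  angle_pmax_e 48.38
#>   projection 70.0%  (undershoot)  log length diff -0.0427

mc_effect_sizes(comp, names = "angle_pt", n_reps = 2000, seed = 1)$angle_pt
#> <effect_size C1: angle_pt = 25.9695 (observed 24.7422), var 76.36686, 2000 reps>

check_local_adaptation(gen$comparison)[c("local_adaptation", "g")]
#> $local_adaptation TRUE ; $g 0.94
```

The plasticity vector of population A sits 24.7° from the total
phenotypic difference (well below the 90° random expectation) and its
projection accounts for 70% of that difference — plasticity points at,
and undershoots, the locally adapted phenotype. The Monte Carlo mean
(26.0°) with sampling variance 76.4 deg² is what enters the
meta-analysis; g = 0.94 says the local population is nearly one pooled SD
fitter, so the comparison passes the local-adaptation filter.

Pooling a whole synthetic literature:

```r
md  <- generate_meta_dataset(meta_generator_spec(
  k_studies = 34, true_mu = 25, tau2_study = 25, seed = 7))
fit_random_effects(md$dataset, "study")
#> Multilevel meta-analytic model (REML, study random effect)
#> k = 87 effects; tau2_study = 10.6988, tau2_obs = 10.6972
#> Pooled mean: 25.8445  [95% CI 23.9104, 27.7787]

compare_random_structures(md$dataset)$table
#>       structure     aicc    delta
#> study     study 586.8889 0.000000
#> phylo     phylo 592.2797 5.390805
```

The pooled mean recovers the generating 25° within its CI, and the
study-level random structure (the generating one) beats the phylogenetic
alternative by >5 AICc units.

`run_pipeline(pipeline_config(...))` executes the same chain from CSV/
Newick inputs and writes `effects.csv`, per-effect Monte Carlo densities,
`meta_summary.csv` and a reproducibility manifest;
`ancestral_order_sensitivity()` rechecks conclusions under randomized
A/B assignments for ambiguous comparisons. A thin command-line wrapper
lives at `inst/scripts/plastvec-pipeline.R`.

## Package layout

- `R/study_data.R` — CSV schema, validation, trait standardization
- `R/geometry.R` — centroids, P-matrices, vectors, angles, classification
- `R/effect_sizes.R` — Monte Carlo sampling distributions and covariances
- `R/local_adaptation.R` — Hedges' g filter and moderator
- `R/meta_model.R` — multilevel REML fits, phylogenetic matrices, AICc
- `R/synthetic_data.R` — generators with closed-form ground truth
- `R/pipeline.R` — orchestration, sensitivity analysis

See `vignettes/plasticity-vectors.Rmd` for the full model description,
assumptions, numerical choices and validation design.
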