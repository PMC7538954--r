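---
title: "Reference models for the area under the expiratory flow-volume curve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference models for the area under the expiratory flow-volume curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aexref)
library(dplyr)
```

## The measurement

Spirometry interpretation compares measured lung function against predicted
values and a lower limit of normal (LLN) derived from healthy reference
populations. The area under the maximal expiratory flow-volume curve,

$$AEX = \int_0^{FVC} \dot V \, dV \quad [\mathrm{L^2/s}],$$

summarizes the whole expiratory effort in a single number: it grows with
both the vital capacity (the curve's width) and the achievable flows (its
height), and its shape sensitivity makes it a candidate global index of
ventilatory impairment. When equipment does not export the sampled curve,
AEX can be approximated by the polygon through spirometric landmarks: the
origin, the peak (FEV_PEF, PEF), the instantaneous flows FEF25/FEF50/FEF75
placed at 25/50/75% of exhaled FVC, and the terminal point (FVC, 0).
`aex_approx()` implements the four nested approximations — AEX1 (FVC and
PEF only), AEX2 (adds FEF50), AEX3 (FEF25 and FEF75), AEX4 (all three) — as
triangle-plus-trapezoid sums, and `integrate_flow_volume()` integrates a
sampled trace by the trapezoidal rule. The two routes agree exactly on
polyline data, which is the backbone of the package's test suite.

Two geometric facts drive everything else:

* **Refinement**: inserting a node whose flow lies below the chord of the
  current polygon strictly decreases the area; real expiratory curves are
  scooped (convex descending limb), so finer approximations shrink —
  AEX1 > AEX2 > AEX3 ≳ AEX4.
* **Scale equivariance**: scaling all flows (or all volumes) by c scales
  every AEX by c, so the statistic inherits the units L²/s.

When the volume at peak flow is missing, `estimate_fev_pef()` supplies the
FEV1-based estimate `0.157174 + 0.176439 * FEV1`; approximations computed
from it are flagged per row (`used_estimated_fev_pef`), mirroring the
starred convention of published tables.

## Reference models

Three model families produce predicted AEX and AEX z-scores from gender,
race, age, height and weight:

1. **Stratified moments** (`fit_stratum_stats()`, `z_score()`,
   `is_below_lln()`): per gender-by-race mean and SD (n − 1 denominator)
   define z = (x − mean)/sd; the LLN is z < −1.645, the 5th percentile of
   the standard normal. The threshold is strict: z = −1.645 exactly is not
   below the LLN.
2. **Stratified least squares** (`fit_stratified_linear()`): one OLS fit per
   stratum, optional backward elimination at α = 0.05 (off by default —
   reported reference equations typically keep all anthropometric terms
   unless clearly null). `fit_regularized()` adds outcome transforms (log,
   or a Gamma GLM with log link — our reading of "gamma transformation",
   with the plain log transform as the alternative) and ridge / lasso /
   elastic-net / double-lasso penalties via glmnet. The double lasso uses
   the conservative one-standard-error rule for its selection stage and
   re-fits on the survivors; penalty strength 0 reproduces OLS exactly, so
   the penalized family nests the unpenalized one.
3. **Mixed-activation neural network** (`train_ann()`): a small multilayer
   perceptron whose hidden layers mix three node families — sigmoidal
   (tanh), linear (identity) and gaussian (`exp(-u²)`) — with the default
   architecture of two hidden layers of (3, 3, 3) nodes each. Training
   minimizes the penalized criterion `Σ loss(residual) + λ Σ w²` by BFGS
   with analytic gradients from seeded uniform(−0.1, 0.1) initial weights.

Published equation sets (ECSC, NHANES III, GLI-style, or older AEX
equations) plug in through `read_equation_set()`: JSON files with
per-stratum affine-or-log-affine formulas and validity ranges. The package
ships only an empty template — the coefficients belong to their source
publications — and composite targets (predicted AEX1–AEX4) are built by
predicting the component flows and volumes first and then delegating to the
same polygon geometry as the measured values.

### Choices a user should know about

* **Sigmoidal = tanh**, with the logistic form deliberately not offered as a
  separate option; tanh is the zero-centered variant the reference software
  family uses. **Gaussian = `exp(-u²)`** of the affine input, the standard
  radial node.
* **Penalty λ** is expressed on the summed standardized-outcome scale
  (outcome standardized internally, weights penalized, biases not). The
  default λ = 5 was chosen as the order of magnitude at which validation
  performance plateaus on cohorts like the packaged presets — roughly
  λ/n ≈ 3·10⁻³ at the preset training sizes. λ = 0 recovers the
  unpenalized fit; a linear-only architecture then reproduces OLS.
* **Robust loss** = Huber with δ = 1.345 × a preliminary residual scale
  (MAD of a linear pilot fit), selectable per fit; squared error is the
  default. **Transformed covariates** = rank-based normal scores of the
  continuous inputs, off by default.
* **Convergence**: relative objective change below 1e-8 or 5000 BFGS
  iterations; non-convergence returns the model with a warning flag rather
  than an error. Identical seed and data give bit-identical weights.
* **Boosting** (`train_boosted()`): 100 stages of a one-layer (2, 2, 2)
  base learner on the running residuals, shrinkage 0.1; stage m uses seed
  `seed` for m = 1 (so a 1-stage, rate-1 ensemble coincides with a single
  fit) and a derived child seed afterwards.
* **Partitions** (`make_partition()`): 67/33 random holdback, 50/25/25
  pooled, or the external scheme (derivation cohort split 67/33, every
  other cohort's row becomes external validation).
* **Model degrees of freedom** in RMSE (`eval_metrics()`): RASE divides by
  n, RMSE by n − model_df, with model_df = fitted coefficients for linear
  models and weight count for networks. This is the only convention under
  which both columns of the usual comparison tables are simultaneously
  meaningful, and it is configurable.
* **Residual mean CIs** use Student t by default; because AEX residuals are
  typically non-normal, a seeded 2000-resample bootstrap interval is
  available (`ci = "bootstrap"`). Heteroscedasticity is flagged by a
  one-sided Spearman correlation between |residual| and prediction at
  p < 0.05 — the "residuals not progressively larger at higher values"
  criterion.
* **Importance** (`total_effects()`): variance-based total effects with
  dependent inputs. A probed factor's substitute values are drawn uniformly
  from the k = 5 nearest neighbours of the complementary factor vector
  among observed rows (Euclidean distance on standardized continuous
  factors; a categorical mismatch adds 1.0 standardized unit, a documented
  and configurable convention), and the Jansen estimator
  `E[(y − y')²]/2` of each total effect is normalized so shares sum
  to 100. This respects the strong gender-height and age-cohort
  correlations that make independent-input Sobol sampling misleading on
  anthropometric data.
* **z-score models**: a network trained with `output = "zscore"` learns the
  stratified z-surface and reconstructs AEX as `mean + z·sd` at prediction
  time, so the LLN decision and the prediction share one model.

## The synthetic cohort generator

No subject-level spirometry data ship with the package; `generate_cohort()`
creates cohorts with the statistical structure the pipeline assumes, making
every stage testable offline. Two presets emulate the populations such
reference models are typically derived on: `cleveland_like_spec()` (n =
3111, ~66% women, 13% Black, age 53 ± 15 y, height 166 ± 10 cm, weight
82 ± 20 kg) and `madrid_like_spec()` (n = 457, 61% women, all White, age
73 ± 5 y, height 158 ± 9 cm, weight 70 ± 12 kg).

The generator draws anthropometry from truncated normals (±4 SD and
positivity; a spec whose truncation keeps less than half the mass is
rejected as infeasible), then builds landmarks from a structural surface:

* log FVC and log PEF are linear in height and age (10-cm / 10-y units
  centred at the preset's reference values) with a quadratic age term, a
  gender offset, a gender × height interaction, a race offset and a small
  weight term, plus lognormal noise (σ = 0.12 for FVC, 0.18 for PEF);
* FEV1 and the FEF flows follow ratio chains (FEV1/FVC, FEF25/PEF,
  FEF50/FEF25, FEF75/FEF50) with mild age trends, small gaussian jitter and
  hard clamps that enforce per-row physiology: FEV1/FVC in [0.70, 0.95],
  FEF25 ≥ FEF50 ≥ FEF75, 0 < FEV_PEF < 0.25 FVC;
* measured AEX is the exact area of a scooped curve through all six
  landmark nodes — exponential-in-volume segments that lie below every
  chord for shape > 0 and reduce to the straight polyline at shape = 0 —
  times lognormal noise with σ = 0.03. `make_flow_volume_trace()` samples
  the same curve family densely for trace-level tests and plots.

All structural coefficients are synthetic, labelled as such in the preset
files, and editable. The intercepts were calibrated once so the cohort AEX
means land near 11.9 and 7.3 L²/s, the values reported for populations of
this composition, with the FVC/PEF balance kept near the corresponding
landmark means; the quadratic age curvature (−0.030 and −0.040 per decade²
on the log FVC and log PEF scales) was likewise fixed once, at a strength
that makes the anthropometry-to-AEX surface as non-additive as flexible
models find real spirometry to be — strong enough that a well-regularized
network out-predicts the stratified linear fit by several R² points. The
two presets intentionally carry different surfaces (the elderly cohort is
not an age-slice of the clinical one), so a model derived on one cohort
degrades on the other; this synthetic "cohort effect" is what the pooled
50/25/25 workflow is meant to remove.

The ratio-chain noise is deliberately small (σ ≈ 0.01): its job is to keep
every generated row geometrically consistent (the scooped node ordering
above holds in > 99% of rows), not to emulate the large independent
test-to-test variability of mid-expiratory flows in real data. Consequently
the generator understates FEF-specific variance, and passing tests say
nothing about cohorts whose flow ratios are measured with realistic error.
Other known gaps to real data: no intra-individual repeat-test
variability, no measurement rounding, gaussian-by-construction
anthropometry, and only two race categories.

## What the checks show, and at what sizes

The package's own validation (the test suite and `scripts/acceptance.R`)
runs entirely on generated data at documented sizes chosen for fast,
single-core execution:

* geometry: 1000 random landmark sets against the trapezoid oracle at
  relative 1e-6, and 1000 below-chord insertions for strict monotonicity;
* LLN: the −1.645 threshold against the normal quantile and the 5% ± 0.5%
  tail of 10⁵ simulated z-scores;
* regression: exact (1e-6) recovery of the structural surface on noiseless
  cohorts, and ≥93% per-coefficient CI coverage over 200 replicates at
  n = 500;
* network: OLS nesting at λ = 0 within 1e-4 RASE; across 20 seeds at
  n = 3000, mean validation R² ≥ 0.75 and an R² advantage of ≥0.03 over the
  stratified linear model in ≥80% of seeds;
* pooling: across 20 seeds with 1200 + 300 row cohorts, the pooled
  50/25/25 model matches or beats the externally-validated model on the
  smaller cohort's validation slice in ≥80% of seeds;
* importance: shares sum to 100 ± 0.5 and a single-relevant-input model
  concentrates ≥95% of the share on that input.

These demonstrate internal correctness and qualitative fidelity of the
modelling claims on data the generator produces; they are not a
re-derivation of any published cohort's numbers.

## A worked run

```{r worked, eval = FALSE}
cohort <- generate_cohort(cleveland_like_spec(n = 1500), seed = 1) |>
  add_aex()

part <- make_partition(nrow(cohort), "pooled-50-25-25", seed = 1)
fit <- train_ann(cohort[part == "train", ], seed = 1)

valid <- cohort[part == "validation", ]
eval_metrics(observed = valid$aex, predicted = predict(fit, valid))

total_effects(fit, cohort[part == "train", ], seed = 1) |>
  autoplot()
```

## Limitations

The network is intentionally small and trained by full-batch BFGS: it is a
reference-equation engine, not a deep-learning framework (no GPU, dropout,
or architecture search beyond `run_ablation()` grids). The optimizer's
iteration budget and initialization are package conventions — the
optimization problem is non-convex, and two numerically equivalent training
set-ups can land on optima that differ at the third decimal of a
prediction. GAMLSS-style percentile-curve machinery is out of scope; the
equation-set interface accepts its point predictions but does not re-derive
spline models. Pediatric ranges, bronchodilator-response logic and
inspiratory-loop areas are likewise out of scope.
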