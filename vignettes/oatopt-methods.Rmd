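---
title: "Methods: oat-dispersal optimization and weighted ensemble fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oat-dispersal optimization and weighted ensemble fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oatopt)
```

## Overview

`oatopt` implements a bound-constrained population metaheuristic modeled on
the dispersal of animated oat seeds, its genetically enhanced variant, and
the soft-voting ensemble machinery that the optimizer was designed to
drive: simplex-constrained weight tuning of classifier probability
matrices. This vignette documents the model, every tunable parameter, the
numerical conventions, what the synthetic generators do and do not
emulate, and the design decisions taken where the underlying algorithm
description leaves the behavior open.

## The oat-dispersal optimizer

A population of `N` candidate positions `X` in the box `[LB, UB]^Dim` is
initialized uniformly, `x_ij = r (UB_j − LB_j) + LB_j`, `r ~ U(0,1)`. Each
iteration `t` of `T` recomputes four dynamic parameters: seed mass
`m = 0.5 r / Dim`, awn length `L = N r / Dim`, eccentricity
`e = 0.5 r / Dim` (fresh `r` each) and the deterministic decay
`c = 1 − (t/T)^3`, which anneals every stochastic move from full strength
at `t = 0` to zero at `t = T`.

Three moves act on individuals:

* **Wind dispersal (exploration).** A perturbation
  `W = (c/π)(2 r_Dim − 1) ⊗ UB` is added to an anchor chosen by the index
  split `mod(i, s)` with `s = max(1, floor(N/10))`: the population mean
  (`mod = 0`), the incumbent best (`mod = 1`) or the individual itself
  (otherwise). With a 1-based index this sends roughly one in `s`
  individuals to each special anchor. When `N < 20` the step degenerates
  to `s = 1` and every index falls in the population-mean branch; we keep
  this literal behavior rather than inventing a secondary split.
* **Hygroscopic rolling (exploitation).** Amplitude
  `A = UB − |UB · t · sin(2πr)/T|`, displacement
  `R = (m e + L²) · U(−A, A)/Dim`, proposal
  `X_best + R + c · Levy(Dim) ⊗ X_best`.
* **Elastic jumping (exploitation).** Amplitude uses `cos` in place of
  `sin`; one fresh scalar `r` drives the awn elasticity `k = 0.5 + 0.5r`,
  length change `x = 3r/Dim` and launch angle `θ = πr` (the defining
  equations reuse a single symbol `r`, and we read that literally); drag
  `α = e^{r'/T}/π` with `r' ~ U(0, T)`, so `α ≤ e/π < 1` and the factor
  `(1 − α)` never flips sign. The displacement divides by `m g`; since `m`
  can be arbitrarily small, it is floored at `1e−12`.

Every proposal is clipped to the box — the original description is silent
on boundary handling, and clipping is the convention that keeps the
amplitude formulas (which reference `UB` directly) meaningful.

**Lévy flights.** Steps are `0.01 μ σ / |ν|^{1/β}` per coordinate with
`ν ~ N(0,1)` and stability exponent `β = 1.5` by default. The scale `σ`
follows the algorithm's printed form, which differs from the standard
Mantegna scheme in two respects: `π` appears in the denominator where
Mantegna has `β`, and the root exponent is written with an undeclared
symbol that we read as `β` (the only parameter in scope). The printed form
with `μ ~ U(0,1)` is the default (`levy_variant = "literal"`,
`σ ≈ 0.4255` at `β = 1.5`); the Mantegna scheme with `μ ~ N(0, σ²)` and
`σ ≈ 0.6966` is available via `levy_variant = "mantegna"`. Both are
implemented because the intended form is genuinely ambiguous; the choice
only rescales the exploitation noise.

One further printed convention we preserve: exploitation proposals anchor
at `X_best` and add `c · Levy ⊗ X_best`. This term vanishes in any
coordinate where `X_best = 0`, so pure Lévy refinement stalls exactly at
the origin. On origin-centered test functions convergence is then carried
by the genetic operators (below), which is consistent with the enhanced
variant's motivation.

**Scheduling.** The published pseudocode does not pin down how individuals
are assigned to exploration vs exploitation. We use a per-individual
Bernoulli draw: exploration with probability `p_explore` (default 0.5),
then rolling vs jumping with probability `p_roll` (default 0.5, matching
the "equiprobable outcomes" description). Both probabilities are exposed
in `eaoo_config()` so other schedules can be emulated.

**Genetic enhancement.** After the oat moves, two operators sweep the
population, each followed by greedy replacement (`f(U) ≤ f(X)` keeps the
trial; non-finite trials are rejected):

1. differential crossover: rand/1 mutant `V = X_r1 + F(X_r2 − X_r3)` from
   three distinct partners, binomial crossover at rate `CR` with a forced
   coordinate;
2. non-uniform mutation: each coordinate mutates with probability `Pm` by
   `Δ(t, y) = y (1 − r^{(1−t/T)^b})` toward a bound on a fair coin flip —
   the step is a fraction of the distance to the bound, so feasibility is
   preserved by construction, and `Δ(T, y) = 0` exactly.

Crossover precedes mutation because the enhancement is described in that
order and both share the same greedy acceptance. Setting
`use_ga_operators = FALSE` recovers the plain algorithm, which is the
ablation switch used in the tests.

**Defaults.** `N = 50`, `T = 100`, `F = 0.5`, `CR = 0.9`, `Pm = 0.1`,
`β = 1.5` follow the published benchmarking settings for this algorithm
family; `b = 5` is the conventional non-uniform-mutation degree and
`g = 9.81` the obvious gravitational constant, neither being stated in the
source description. The incumbent best is replaced only on *strict*
improvement, so on plateaus the first optimum found is retained — a
property the ensemble layer relies on (see below).

## Reference optimizers

Differential evolution (rand/1/bin, `F = 0.5`, `CR = 0.7`), a real-coded
genetic algorithm (tournament of 3, arithmetic blend crossover at 0.8 with
a fresh mixing coefficient per mating, per-gene uniform reset at 0.1,
elitism of one) and uniform random search share the optimizer contract:
same config/result shapes, monotone best-so-far history, clipping, seeded
reproducibility. The GA's crossover operator is not specified in the
benchmarking settings we mirror; arithmetic blending is the standard
real-coded choice. These exist as comparison baselines, not contributions;
further comparators (grey wolf, whale, sine-cosine, Bayesian search) were
deliberately left out.

## Ensemble weight fusion

Candidates are box points in `[0,1]^M` projected by clip-then-normalize
onto the simplex; an all-zero candidate maps to uniform weights. This
keeps the optimizer purely box-constrained instead of introducing a
constrained search space. The accuracy objective is piecewise constant in
`w` (it changes only when some row's argmax flips), which is exactly the
regime where gradient-free search is appropriate; the cross-entropy
objective is smooth and is provided as the alternative fitness. Accuracy
is the default because it is the quantity the fusion weights are meant to
maximize.

The initial population is warm-started with the uniform vector and all
`M` one-hot vectors. Two consequences:

* the optimized objective can never be worse than the unweighted mean rule
  or any single model — the comparison against conventional rules is
  therefore an inequality by construction, not a statistical accident;
* on plateaus of the accuracy objective (e.g. when one base model is
  perfect and a whole region of the simplex achieves accuracy 1), the
  strict-improvement best rule keeps the first optimal point evaluated,
  which is the one-hot on the perfect model. Planted-model recovery is
  thus exact rather than approximate.

Conventional rules (mean, product with per-row renormalization, hard
voting with ties to the lowest class index, per-cell max, best single
model, accuracy-proportional fixed weights) share the same result type.
All argmax decisions break ties toward the lowest class index,
everywhere. Labels are 1-based integers, the R convention.

## Attention and activation-map math

The squeeze-and-excitation block is implemented as pure array math:
squeeze is the spatial mean per channel; excitation is
`sigmoid(W2 · relu(W1 · z))` with no bias terms by default (the canonical
gate has none; biases can be supplied), hidden width
`max(1, floor(C/r))` with reduction ratio `r = 16` by default — the
floor/max guard exists because fixture channel counts are small.
Class-activation maps are `relu(Σ_m γ_m F^m)` with channel weights
`γ_m` equal to the spatial mean of supplied gradient tensors. Gradients
are *inputs*: the package never differentiates a network, which keeps the
module framework-free; tests feed analytic gradients of linear toy
scorers, for which `γ` has a closed form. Min-max normalization of a map
to `[0,1]` is presentation-only and separated from the defining formula by
an explicit flag.

## Preprocessing and balancing

Min-max normalization maps the observed range affinely onto a target
range; a constant image is returned as all-`out_min` with a warning.
Augmentation covers rotation (±10°, about the image center), translation
(≤10% per axis), horizontal flip, and 5×5 Gaussian blur with
`σ = 0.3((k−1)/2 − 1) + 0.8 = 1.1` — the common kernel-size rule, adopted
because the source pipeline says only that `σ` is derived automatically.
Geometric transforms use bilinear interpolation with zero fill and
preserve shape (delegated to EBImage's affine machinery); parameters
outside the stated ranges are rejected rather than silently clamped.

SMOTE brings every class up to the majority count:
`x_new = x_i + λ(x_nn − x_i)`, `λ ~ U(0,1)`, with `x_nn` among the `k = 5`
Euclidean nearest same-class neighbors (`k` shrinks to `n_c − 1` for tiny
classes; a singleton minority class is an error since interpolation is
undefined). Original rows are preserved verbatim and flagged, and every
synthetic point lies on a segment between two class members, hence inside
the class's bounding box — both properties are tested exhaustively.
SMOTE operates on whatever feature columns the caller supplies; the
package does not prescribe an embedding.

## Synthetic generators and what they do not show

`simulate_prediction_matrices()` emulates confident softmax outputs: each
row is `(1 − s) · Dirichlet(1,…,1) + s · onehot(predicted)` with sharpness
`s ∈ (0.5, 1]` (default 0.8), so the planted argmax is guaranteed; the
predicted class is the truth with the model's target accuracy, otherwise
a uniformly wrong class. Error correlation is induced by letting models
share a per-sample difficulty draw with the stated probability, which
leaves marginal accuracies untouched. This captures the structure that
matters for weight optimization — per-model accuracy and error overlap —
but *not* the calibration profile, class-conditional error structure, or
feature-level correlations of real CNN ensembles; passing tests show the
optimizer and fusion math are correct, not that any particular clinical
accuracy is attainable. The imbalanced-cluster generator defaults to the
420/312/90 three-class shape as its reference imbalance scenario, with
well-separated isotropic Gaussian blobs at unit spread — intentionally
easy for SMOTE, since the tests target the balancing contract, not
classifier performance.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the optimizer at its default
study conditions (population 50, 100 iterations) for the convergence and
ablation checks: 5 seeds on the 5-D sphere, 10 seeds per variant on the
10-D Rastrigin, 5 seeds for the two-model grid-equivalence and
planted-recovery scenarios at 60 samples, and 150 samples for the
weighted-vs-mean comparison. These sizes were chosen to make the binomial
and convergence margins comfortable. Other conventions:

* non-finite objective values are treated as `+Inf` (rejected by greedy
  selection);
* probability rows are validated to sum to 1 within `1e−6` and
  renormalized (file readers can be made strict, and the run drivers are);
* cross-entropy floors probabilities at `1e−12` before the log;
* maximization is handled by negation at the interface, minimization is
  the internal convention throughout;
* seeded runs restore the ambient RNG state afterwards
  (`withr::with_seed`), and all sub-seeds derived by the drivers stay
  below `2^31`.

## Known limitations

* The literal Lévy scale and the `X_best`-anchored exploitation are kept
  as printed; both are debatable readings of an ambiguous description and
  are therefore switchable or documented rather than silently corrected.
* The plain (non-enhanced) variant exploits around the incumbent best with
  heavy-tailed noise and has weak refinement near the origin; it is
  retained as the ablation baseline, not as a recommended optimizer.
* The accuracy objective's plateaus mean reported "optimal" weights are
  one representative of an optimal region, stabilized by the warm start
  and strict-improvement rule rather than unique.
* No constraint handling beyond the box and the simplex projection; no
  parallel evaluation.
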