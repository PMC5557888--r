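---
title: "Multilevel evolution of protocell replicators: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel evolution of protocell replicators: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protosym)
```

## The model

`protosym` simulates a closed system of `N` particles — self-replicating
molecules ("replicators") and the substrates they are built from — partitioned
into protocells. Replicators come in two complementary strands, plus (P) and
minus (M); replicating a P template yields an M product and vice versa. Each
replicator carries four complex-formation rates `k_xy` (`x, y ∈ {P, M}`): the
rate at which it, acting as catalyst of strand `x`, binds a template of strand
`y`. Two of the four values describe the molecule itself, the other two its
complement, so the full heredity of the pair travels with every copy.

Replication is a two-step process. Two free replicators first form a
catalyst–template complex (rate `k_xy` of the catalyst); the complex then
converts one substrate of the same protocell into a complementary copy of the
template, after which it dissociates. While bound, a catalyst cannot serve as
template — catalysis therefore carries an opportunity cost, and within a
protocell selection favours replicators with *low* `k_xy` (selfish templates).
Protocells, in contrast, grow by attracting the freely diffusing substrates in
proportion to how fast they consume them, and a protocell reaching `V`
particles splits in two; selection *between* protocells therefore favours
*high* `k_xy`. The tension between these two levels is the object of study:
for intermediate `V` it spontaneously breaks the symmetry between the two
strands, producing a catalytic, high-copy strand and a non-catalytic,
low-copy "genome-like" strand.

### The reaction algorithm

One time step consists of reaction, diffusion and division sub-steps. The
reaction sub-step iterates `N/α` micro-iterations. Each micro-iteration picks
a particle X uniformly among all `N` particles, then a partner Y uniformly
among the other particles of X's protocell (excluding X's complex partner; if
no eligible Y exists only X's decay is attempted). A single uniform draw then
selects at most one event by cumulative thresholds:

* complex formation, probability `α β k_xy^X` (X catalyses Y) or `α β k_yx^Y`
  (Y catalyses X), with `β = 1/2` cancelling the two selection orders of a
  pair;
* replication, probability `α γ` when one pick is a complex member and the
  other a substrate, with `γ = 1/4` cancelling both the two selection orders
  and the two-fold pick chance of a dimer;
* decay of a replicator X into a substrate, probability `α d`.

`α = 1/(k_max + 1/4 + d)` caps the summed probabilities at one
(`computeAlpha()`). Because one uniform draw is compared against cumulative
thresholds, realised event frequencies are *exactly* proportional to the rate
constants `k_xy : k_yx : 1 : d`; the test suite checks the resulting event
statistics against closed-form propensities and geometric/exponential waiting
times, i.e. against the continuous-time (Gillespie) description of the same
network on a single compartment. Replication converts a substrate into a
replicator and decay does the reverse, so `N` is conserved exactly — asserted
over 10⁴ steps in the tests. When rates are unbounded (the lineage assays),
`α` is recomputed each step from the current maximum effective rate, which
keeps probabilities valid without biasing relative rates. The residual
fraction of `N/α` is carried stochastically (one extra iteration with the
fractional probability), so the expected iteration count is exact.

In the diffusion sub-step all substrates are pooled and redistributed
multinomially with weights equal to each protocell's replicator count (the
limit of fast substrate diffusion through cell membranes); a replicator-free
cell receives nothing. In the division sub-step every protocell at or above
`V` particles splits, each particle assigned to a daughter with probability
1/2. A complex is one physical dimer, so it is assigned as a unit by default
(`split_complex_units`; a dissociate-at-division switch is provided since
either convention is defensible). Empty protocells are removed.

### Mutation

A freshly replicated molecule inherits the template's four `k_xy` values and,
with probability `m`, mutates them. Three methods are implemented
(`mutation_method`): the default adds an independent `Uniform(−δ, δ)` step to
each value, reflecting at the upper bound `k_upper = 1` and unbounded below —
stored values may go negative, in which case the *effective* rate is zero.
This removes any boundary artefact at `k = 0`, which matters because the
symmetry-broken state lives exactly at that boundary. The alternatives
(reflecting at zero; multiplicative steps in log scale) exist to show the
results are not artefacts of the boundary convention.

A mutation event perturbs all four values, each with its own draw
(mutations of the two strand aggregates are small and uncorrelated, which is
what the mutational-variance decomposition below assumes); a switch
(`mutate_all = FALSE`) restricts the event to one randomly chosen value
instead, since the alternative convention is equally plausible.

Symmetry constraints can be imposed for mechanism dissection
(`symmetry_mode`): `kinetic` ties `kPP = kPM` and `kMP = kMM` (both strands
replicated at equal rates), `functional` ties `kPP = kMP` and `kPM = kMM`
(both strands equally catalytic), `both` ties all four. Ties correlate
mutation steps and would inflate the variance of `Σ k_xy` — effectively
raising the mutation rate — so each tied group of size `n` is perturbed by
the mean of `n` independent draws. The identity
`Var(Δ Σ k_xy) = 4δ²/3` in every mode is checked by Monte Carlo in the
acceptance suite.

### Model variants

* `one_step`: a successful catalyst–template encounter converts a substrate
  immediately (if one is present in the cell); no complex persists, so
  catalysis costs nothing at the molecular level. This removes the
  multilevel conflict: the tests verify that high-`k` replicators suffer no
  within-cell disadvantage in this variant, while they are visibly exploited
  in the two-step model.
* `cross_chiral`: four classes `L_P, L_M, D_P, D_M`; complex formation is
  allowed only between opposite chiralities (rates still read from the
  catalyst's `k_xy` by strand), replication preserves chirality while
  complementing the strand, and both chiralities share one substrate pool.

## Parameters

| Parameter | Meaning | Default |
|---|---|---|
| `V` | division threshold (particles) | per experiment, 10²–10⁴ |
| `N` | total particles (conserved) | `50 V` |
| `m` | mutation probability per replication | 0.01 |
| `delta` | mutation step half-width | 0.05 |
| `d` | decay probability per time step | 0.02 |
| `k_upper` | reflecting upper bound on `k_xy` | 1 (`Inf` in lineage assays) |

With `N = 50V` the protocell count is independent of `V`, so `V` tunes the
strength of intracellular drift without changing the strength of
between-cell selection. All defaults are set in `protocellParams()` and
never tuned per run.

## Measurement assays

**Division counting.** `runLineage()` follows one protocell along its line of
descent against an infinite, stationary background population: the diffusion
sub-step is replaced by drawing the cell's substrate count from
`Poisson(n_R · N'_S/N'_R)`, and at each division one daughter is kept at
random. As its internal replicators degrade (molecular-level evolution), the
cell loses its initial advantage and eventually stops dividing; the number of
divisions along the line of descent measures how slowly that degradation
runs. `calibrateInitialK()` makes different asymmetry profiles comparable by
scaling each profile so a closed pilot cell reaches the same stationary
replicator density (bisection against `closedCellDensity()`; a mean-field
fixed point is nontrivial here because complex occupancy feeds back on the
free-template pool, so a pilot simulation is used instead). The pilot
exposes a genuinely bistable density range: below a threshold rate the closed
cell collapses, so densities inside the gap are reported as unattainable
rather than silently mis-calibrated.

**Growth restoration.** `estimateRestorationProbability()` repeats the
lineage assay with a non-catalytic minus strand (`kMP, kMM < 0`) and scores
the fraction of lineages that divide again after shrinking below `0.3 V`
particles — drift in a severe bottleneck occasionally purges the degraded
replicators and restores growth. The kinetic asymmetry
`κ = (kPM − kPP)/(kPM + kPP)` is the independent variable; `κ = 1`
(`kPP = 0`) is a structural impossibility since the plus strand is then never
produced, and the tests assert that no lineage survives it.

**Analysis.** `asymmetryMetrics()` computes κ, the copy-number asymmetry
`θ = (N_P − N_M)/(N_P + N_M)` and the functional asymmetry
`a_f = (k_P − k_M)/(k_P + k_M)`; `effectivePopulationSize()` implements the
variance effective size `N_e = 2(1/N_P + 1/N_M)⁻¹` of an alternating-strand
population; `mutationalVariance()` evaluates the first-order decomposition
`σ_f² ≈ (∂f/∂k_P)² σ_kP² + (∂f/∂k_M)² σ_kM²` with a pluggable gradient
estimator, zeroing a term whenever the corresponding mean aggregate is
negative. `classifyPhase()` labels runs `symmetric`, `broken` or `extinct`;
the broken label requires time-averaged `|a_f| > 0.5` *and* a minor-strand
aggregate statistically indistinguishable from zero — the 0.5 threshold is
this package's operationalisation of what is a by-eye classification in the
original analysis, and it is exposed so its sensitivity can be checked.
`phaseScan()` sweeps `(m, V)` and `boundarySlope()` fits `log m*` against
`log V` at the symmetric/broken boundary, where the scaling `mV ∝ 1/V`
predicts a slope of −2.

## The minimal hierarchical Moran model

`runMinimal()` strips the system to its sufficient core: replicators carry a
cooperativity pair `(k1, k2)`, live in protocells that split binomially above
`V` members, and evolve by a Moran process — each step one replicator
replicates with probability proportional to
`f = exp(k̄1 + k̄2 − r(k1 + k2))` (per-cell means `k̄`; `r` the relative cost
of cooperation, default 0.3 from the stated range `0 < r < 1`) and one dies
uniformly at random (drawn before the birth is placed, so population size is
exactly constant; a within-cell-death switch exists for sensitivity
analysis). In the `rectified` variance mode every `k` entering `f` is clamped
below at zero, so `∂f/∂k_i = 0` for `k_i < 0` and the mutational variance of
`f` collapses as a value reaches the boundary; in the `invariant` mode no
clamping is applied and the variance of `f` is position-independent.

The desk-scale demonstration uses `V = 300`, `n_total = 20 V`, `m = 0.2`,
`δ = 0.1`, started from `k1 = k2 = 0.3` and run for 8×10⁶ steps (about 1 300
population turnovers), with `V = 100` as the small-cell reference. These
values were chosen once, as the smallest system in which the three regimes
separate cleanly within minutes of CPU time, and then frozen. In rectified
mode, `V = 100` keeps both values high and symmetric while `V = 300` pins
one value at the zero boundary and maintains the other by cellular selection
— the asymmetry index `|(k1 − k2)/(k1 + k2)|` (computed from the clamped
population means) rises towards 1. In invariant mode no such stable broken
state forms at either `V`: at `V = 300` both values decline together without
bound, which is why the index itself is only meaningful while total
cooperativity is positive; the acceptance suite therefore asserts the
*absence of the broken configuration* (pinned minority with maintained
majority) rather than a value of the index in that regime.

## Numerical choices and degenerate inputs

* Event selection uses one uniform draw against cumulative thresholds, making
  relative frequencies exactly proportional to rate constants (a sequential
  conditional scheme would bias the second orientation by `O(αβk)`).
* Reflection at bounds is iterated, and performed in log space for the
  multiplicative method, preserving the random-walk character on each scale.
* Asymmetry ratios with non-positive denominators are flagged undefined
  (`NA`) rather than clamped.
* A protocell whose only eligible partner for X is X's own complex partner
  attempts only decay, per the reaction rules; lone substrates do nothing.
* In the Moran engine, per-cell aggregate sums are rebuilt periodically to
  stop floating-point drift of incremental updates, and exponent arguments
  are clamped at ±50 to avoid overflow in the unbounded invariant mode.
* Strand relabelling in summaries maps `kPP ↔ kMM`, `kPM ↔ kMP` and
  `N_P ↔ N_M`, so reports are invariant under the arbitrary choice of which
  strand broke.

## Scope of the synthetic tests

All tests run on systems generated in code at the sizes stated above
(`V ≤ 2000`, `N ≤ 10⁵`, ≤ 2×10⁵ time steps; the published phase boundaries
at `V` in the thousands with ≥10⁷-step equilibration are cluster-scale and
are not re-measured here). The suite therefore demonstrates the mechanics —
conservation, exact event statistics, directionality of the two selection
levels, the minimal model's symmetry breaking, assay plumbing — rather than
the full phase diagram. One known quantitative deviation is documented: with
`N = 50V` the equilibrated protocell count measures ≈1.35 × 2N/V rather than
2N/V (the cell-size distribution carries substantial mass below `V/2` from
shrinking cells; `2N/V` assumes a mean cell size of `V/2`). The measured
value, not the nominal one, is what `scripts/acceptance.R` reports.

## Limitations

Replicators carry rate constants, not sequences; there is no
genotype–phenotype map, no spatial structure within or between protocells,
and no external resource flux (the system is closed; substrates arise only
by decay). Parasite emergence and folding-based fitness are out of scope.
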