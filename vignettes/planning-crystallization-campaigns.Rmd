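---
title: "Planning crystallization campaigns: models, objectives and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning crystallization campaigns: models, objectives and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystplan)
```

`crystplan` steers batch cooling crystallization experiments toward target
kinetics — induction time, nucleation rate, growth rate — over a
two-dimensional design space of supersaturation ratio `SS` (dimensionless,
1 at equilibrium solubility) and isothermal temperature `T` (°C). This
vignette documents the models behind the two planners, every tunable that
matters, the assumptions of the virtual laboratory, and the design decisions
taken where more than one reasonable construction existed.

## The kinetic relations

Five marginal relations connect the kinetics to the inputs. Induction time
falls steeply with supersaturation, and nucleation is thermally activated, so
those two relations are exponential, `A·exp(a·x + b)`; the remaining three
instantiated relations (nucleation and growth vs `SS`, growth vs `T`) are
treated as locally linear, `a·x + b`. No induction-time–temperature relation
is modelled: there is no direct mechanistic dependence, and the registry
(`relation_registry()`) never instantiates that pair.

Two numerical points about fitting (`fit_relation()`):

* **Identifiability.** `A` and `exp(b)` multiply into one constant, so the
  exponential fit estimates `A` and `a` with `b` pinned to zero. `b` is kept
  in the type so user-specified relations (e.g. virtual-lab truths) can carry
  it.
* **Noise model.** Rate measurements carry multiplicative, roughly lognormal
  error (image analysis samples only a subset of particles), so exponential
  relations are fitted by least squares on the log scale — the
  maximum-likelihood estimator under that noise — and linear relations by
  ordinary least squares on the raw scale.

Predictions are floored at `1e-12` (`eval_relation()`): linear fits
extrapolated across the design space can cross zero, and downstream
logarithms must stay defined.

## Objectives

Both planners minimize a distance between kinetics and targets; they differ
in what the distance is measured on.

* The **DoE objective** (`doe_objective()`) is evaluated on the *fitted
  relations*: exponential relations contribute `|ln P_fit − ln P_target|`
  (symmetric under multiplicative deviation), linear ones
  `|P_fit − P_target|`. The two growth terms are multiplied by
  `growth_weight` (default 10) because growth rates are one to two orders of
  magnitude smaller than the other objectives on their natural scales.
* The **BO objective** (`bo_objective()`) is evaluated on *measured*
  kinetics as a sum of absolute log ratios over the three parameters. The log
  form already places all terms on one scale, so no growth weighting is
  applied by default (`weight_growth` exposes it). Natural logarithms are
  used throughout; the choice is conventional and only rescales both
  objectives uniformly.

A fully censored experiment (no nucleation in any of the cycles) yields no
induction time. Rather than failing, `bo_objective()` returns
`|ln(hold/t_target)| + 2 × max_term_so_far` — large relative to anything
observed, but finite, so the Gaussian-process surrogate stays well behaved
while the region is marked as poor.

## The virtual laboratory

`run_experiment()` emulates one parallel-reactor experiment: `n_cycles = 5`
heat–dissolve–cool–hold cycles, a `hold_s = 10800` s (3 h) isothermal hold,
and imaging every `obs_dt_s = 5` s. Its assumptions, and what they do and do
not capture:

* **Exponential induction times** (memoryless primary nucleation), mean given
  by the truth's induction relation at the condition's supersaturation. Real
  systems can show Weibull-like deviations; passing the package's
  Kolmogorov–Smirnov check therefore validates the sampler against its own
  model, not against any particular laboratory system.
* **Quantization and censoring.** Detection cannot precede an image, so
  induction times are rounded *up* to the 5 s frame; a cycle with no event by
  the hold reports a censored marker, never a number. The per-experiment
  summary is the mean of uncensored cycles.
* **Rate generation.** The truth stores marginal relations (that is what the
  planners fit), so a rule is needed to combine them at a 2-D condition: the
  geometric mean of the two marginal predictions. It is symmetric, positive,
  and reduces to either marginal when the other is flat at the same level.
  One consequence worth knowing: the combined surface spans roughly *half*
  the log-range of each marginal, compressing the objective's dynamic range
  relative to systems whose kinetics genuinely multiply.
* **Noise.** Rates are perturbed by mean-one lognormal noise with
  `rate_noise_cv = 0.2` by default — the scatter typical of image-analysis
  rate estimates. Setting `rate_noise_cv = 0` and `deterministic = TRUE`
  (induction = distribution mean) makes entire planner loops reproducible
  end-to-end, which the convergence tests exploit.

`default_ground_truth()` places every relation's target crossing at
`SS = 2.4`, `T = 25` °C inside lamivudine-style bounds (`SS` 2–3, 5–50 °C):
induction times fall ~20× per unit supersaturation (hours near `SS` 2,
minutes at 3), nucleation rises ~90× across the temperature span (classical
nucleation is strongly thermally activated), growth ~5×. Material accounting
(`material_for_run()`) uses `mass = SS × solubility(T) × volume` with an
exponential solubility–temperature law.

## The adaptive DoE planner

The initial screen is a 5 × 5 full factorial spanning the center ± (0.4, 10 °C)
with three center replicates — 28 runs; follow-up iterations are 2² factorials
plus three centers — 7 runs — with half-widths shrinking to ±0.05 / ±2 °C by
iteration 3 and constant thereafter. Five equally spaced levels per factor is
the natural reading of a five-level design over a stated half-width. Designs
are *clipped* to the bounds rather than rejected, keeping run counts fixed
(28 + 7(k−1) after k iterations).

The fitted surface is minimized by four independent algorithms — a real-coded
genetic algorithm, differential evolution (rand/1/bin), CMA-ES, and
Hooke–Jeeves pattern search; Nelder–Mead is available but excluded from the
default ensemble because on these surfaces it tends to terminate on the box
boundary. Implementations are compact and seeded per algorithm, run on the
unit square so step sizes are scale-free. Solutions on a bound (within 0.1 %
of a span) or non-converged are discarded; survivors aggregate by
**coordinate-wise median**, which ignores a single outlier algorithm where a
mean would be dragged by it. If *every* algorithm lands on the boundary the
minimizer errors (the optimum likely lies outside the bounds); the campaign
catches this and re-centers on the best measured condition, as it also does
when too few uncensored observations exist to fit all five relations.

Refits always use all accumulated data. This stabilizes the surface but makes
early wide-span observations permanent: marginal fits inherit a small Jensen
bias (the mean of `ln(linear)` over a symmetric design is below its center
value), which shrinks quadratically with the design span as iterations
tighten. Termination compares successive *recommended centers*:
strictly less than 0.02 in `SS` **and** 2 °C ("less than" read as strict).

## The Bayesian-optimization planner

The surrogate is a Gaussian process with a Matérn-5/2 kernel, per-dimension
(ARD) length scales, and an observation-noise term — replicated center points
make noise-free interpolation inappropriate. Inputs are normalized to the
unit square; objectives are standardized before fitting. Hyperparameters
maximize the marginal likelihood from three fixed starts (length scales 0.15,
0.3 and 1.0 in normalized units) under box constraints on the logs; a
degenerate training set (one point, or identical objective values) falls back
to fixed moderate hyperparameters and is flagged. Campaigns begin with three
replicate measurements at the starting condition (bounds midpoint by default,
`init_center` to override) taken under distinct derived seeds.

Acquisition is expected improvement for minimization with the improvement
margin shifted by the jitter ξ, maximized by a 101 × 101 grid scan plus a
Nelder–Mead polish from the best cell — exhaustive and deterministic in 2-D.
Flat-acquisition ties break lexicographically (lowest `SS`, then lowest `T`),
and recommendations are kept strictly inside the bounds. Two scale decisions:

* **ξ lives on the objective's own scale**, not the standardized scale. The
  ladder values 0.001–10 span the objective's natural dynamic range
  (log-ratio sums run from ~0.1 to ~10 on these problems), which gives the
  intended spectrum from near-pure exploitation (0.001) to near-pure
  exploration (10). On the standardized scale even ξ = 1 is a full standard
  deviation and every fixed-jitter campaign degenerates into an explorer.
* **"Maximum objective value"** for the adaptive ladder is the maximum
  observed so far in the campaign. The ladder starts at 10, steps to 1 when
  the *latest* objective falls strictly below 10 % of that maximum, to 0.1
  below 5 %, and never rises.

Termination mirrors the DoE rule on successive recommendations. A
`warm_start` argument can seed the surrogate with an initial DoE screen; the
default is three center points only, which keeps the two planners'
experiment counts directly comparable.

## Comparison arithmetic

`grid_search_count()` divides each span by the termination increment (0.02,
2 °C) and multiplies, rounding half-up with no +1 per axis — the count of
resolvable cells (1125 for `SS` 2–3 × 5–50 °C; 1069 for 1.05–2 × 5–50 °C).
`percent_reduction()` rounds half-up to integer percent. Material totals are
sums of per-run masses from the virtual lab's solubility model; they are
reported but depend entirely on the assumed solubility parameters.

## Problem sizes and numerical tolerances used in validation

The test suite exercises: coefficient recovery from 25-point noise-free
screens (relative error < 1e-6) and 200-point screens at 20 % noise
(two-level corner-replicated designs — the D-optimal choice for these
first-order forms — keep every coefficient's sampling error well inside 15 %);
expected improvement against a 10⁶-draw antithetic Monte-Carlo oracle
(absolute error < 1e-3 over a 120-case sweep); the GP posterior against the
closed-form two-point conditional (< 1e-8); induction sampling against the
truncated exponential by Kolmogorov–Smirnov at n = 5000 (observations
de-quantized by subtracting a uniform frame offset before the continuous-CDF
test); DoE convergence on the noise-free default truth within 7 iterations;
and a 20-seed paired adaptive-vs-fixed-jitter comparison on a steep-kinetics
truth (40-experiment budgets, DoE capped at 10 iterations).

## Known limitations

* The geometric-mean rate combination halves each marginal's log-range, so
  the default truth's objective spans only ~0.4–5. Against such a compressed
  range the adaptive ladder's 10 %/5 % triggers are barely reachable; the
  paired planner comparisons therefore use a steeper truth (induction hours →
  seconds across the `SS` span, nucleation vanishing toward the
  metastable-zone edge) where the mechanism is exercisable.
* Under this implementation's noise-aware GP, a fixed jitter of 1 keeps the
  acquisition moving and rarely self-terminates; given an equal experiment
  budget it becomes a long-running explorer, and the paired
  best-objective comparison between adaptive and fixed-1 campaigns is
  close to even rather than clearly favoring adaptive. Adaptive campaigns do
  consistently converge their *recommendations* to the optimum basin and use
  fewer experiments than the DoE loop.
* The virtual lab does not model ramp dynamics, stirring effects, secondary
  nucleation or agglomeration; campaigns against it validate the planners'
  logic, not any specific chemistry.
* The planners handle exactly two input factors; higher-dimensional design
  spaces (cooling rate, antisolvent addition, ...) are out of scope.
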