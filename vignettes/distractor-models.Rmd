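---
title: "Race models of distractor effects: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Race models of distractor effects: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

When people choose between two options (a higher-value option HV and a
lower-value option LV) in the presence of a third, unchoosable
*distractor* D, the distractor's value can either improve or impair the
accuracy of the HV-versus-LV decision.  Two mechanisms predict opposite
effects: feedforward inhibition driven by all options (a high-value D
slows everyone down, extending evidence accumulation and sharpening the
comparison), and divisive normalisation of inputs (a high-value D
compresses the HV/LV drift difference).  This package implements both
mechanisms, a parallel *dual route* combination in which whichever
mechanism first accumulates sufficient evidence determines the choice,
and a two-option *null* model, together with the simulation sweeps,
regression analyses, model-fitting machinery and gaze analyses used to
study where in the decision space each effect predominates.

# The accumulator models

All four models are races between pools of noisy accumulators.  Per
Euler--Maruyama step of length $\Delta t$, pool $i$ receives an input
increment

$$E_{i} \sim \mathcal{N}(d\,V_i\,\Delta t,\; \sigma^2 \Delta t),$$

a common inhibition pool subtracts $I = f \cdot \sum_i E_i / k$ from
every pool, and evidence accumulates as $y_i \mathrel{+}= E_i - I$.  The
first *choosable* pool (HV or LV) whose evidence reaches the threshold
(1.0) determines the choice; the reaction time adds a non-decision time
$T_{nd}$ (0.3 s) to the crossing time.  If no pool crosses within 6 s of
accumulation the trial is undecided and excluded from accuracy analyses.

* **Mutual inhibition**: three pools (HV, LV, D), $k = 3$.  The D pool
  accumulates and feeds the inhibition but can never be chosen.
* **Divisive normalisation**: two pools with drifts
  $d\,V_i/(V_{HV}+V_{LV}+V_D)$, $k = 2$; D enters only through the
  denominator.
* **Dual route**: a mutual inhibition route and a divisive
  normalisation route accumulate independently (independent noise); the
  first route to cross determines choice, RT and the winning route.
* **Null**: mutual-inhibition dynamics over HV and LV only; D is
  ignored.

Parameters carry per-second units: `d` is the drift gain (s\^-1),
`sigma` the input noise SD scaling with $\sqrt{\Delta t}$.  Because the
noise follows the diffusion scaling, results are insensitive to the step
size; the default is $\Delta t = 1$ ms, and the test suite checks that
halving it moves accuracies by less than Monte-Carlo error.

## Numerical choices

* **Tie-breaks.** If both choosable pools (or, in the dual route, both
  routes with different choices) cross within the same step, a fair
  coin decides.  Evidence is not clamped below zero (the simplified
  linear dynamics state no floor).
* **Timeout semantics.** The 6 s indecision limit applies to
  accumulation time, excluding $T_{nd}$, which describes latencies
  before choice information reaches the accumulators.
* **Randomness.** Simulators draw from R's global RNG; `set.seed()`
  before any call reproduces it exactly.  The dual route consumes the
  mutual route's stream first, then the divisive route's, so its
  outcome equals the per-trial minimum of the two standalone routes
  driven by the same streams (tested exactly with `cap_routes =
  FALSE`).  By default the divisive route stops early once the mutual
  route has already decided, which skips only unused noise draws.

## Standard parameters

The decision-space simulations use drift/noise values chosen so that
every model's overall accuracy over the grid is approximately 0.85:
mutual inhibition $d = 1.3, \sigma = 1$; divisive normalisation $d =
5.5, \sigma = 0.6$; dual route $d = 0.8, \sigma = 0.6$ (mutual route)
and $d = 1.0, \sigma = 0.6$ (divisive route); $f = 0.5$ everywhere.
`calibrate_accuracy()` re-verifies the 0.85 anchor and, if a
configuration misses it, reports a bisection-adjusted drift next to the
configured one.

# The decision-space sweep

`value_grid()` crosses value sums $HV+LV \in \{3.0, 3.2, \ldots, 5.0\}$,
differences $HV-LV \in \{0.6, \ldots, 2.0\}$ and relative distractor
values $D-HV \in \{-1.2, \ldots, 4.8\}$ into 1408 cells.
`run_decision_space()` simulates `n_iter` trials per cell and shuffles
iterations uniformly at random into 105 simulated participants
(mirroring the pooled sample size of the empirical data sets the models
are compared against).  Undecided trials are kept for the
undecided-fraction bookkeeping but excluded from accuracy analyses.
Accuracy maps bin by the native grid levels; no re-binning is applied.

The reference analyses in `scripts/acceptance.R` use 500 iterations per
cell.  At that size the Monte-Carlo standard error of the grid-wide
accuracy is about 0.0004, and the group-mean GLM coefficients below are
stable to roughly $\pm 0.01$; the test suite uses the same size.

# The regression suite

`fit_glm()` fits seventeen pre-registered-style specifications
(`"1a"`-`"9"`) per participant; `group_test()` runs one-sample (or
paired) t-tests on the per-participant coefficients.  Conventions that
the numbers depend on:

* Every component regressor is z-scored (sample SD, $n-1$) *within
  participant over the trials entering that fit*, after exclusions.
  Interaction terms are products of z-scored components and are not
  re-scored.
* Trials where the distractor was chosen or no response was made are
  excluded everywhere except the multinomial specification (`"1c"`),
  which retains D choices, needs at least three of them, and flags
  participants with $|\beta| > 10$ on the D-contrast intercept.
* Stepwise specifications (`"2a"`-`"2d"`, `"6b"`, `"6c"`, `"8"`,
  `"9"`) fit step 1, then regress the *response-scale* residuals
  (observed minus fitted probability for logistic step 1) on the step-2
  regressors by ordinary least squares.  Response residuals were chosen
  because the logistic score equations make them exactly orthogonal to
  the step-1 regressors, and because they put the step-2 coefficients
  on the probability scale (magnitudes of order 0.01 for the hard/easy
  distractor effects).
* `median_split()` splits each participant at their median difficulty;
  ties at the median go to the easy side (documented, configurable by
  choosing a different difficulty vector).
* On trial tables mixing distractor and two-option trials, terms
  involving D drop the two-option trials by default
  (`control_d = "exclude"`); `control_d = "mean"` instead assigns the
  mean distractor value to control trials, reproducing the alternative
  convention discussed in the literature.
* The salience regressor $|D|$ is computed on the raw signed value
  before z-scoring, so it is meaningful when gain and loss sessions are
  pooled.
* No multiple-testing correction is applied; p-values are reported raw.
* BIC is $k \ln n - 2 \ln L$ with $k$ counting the intercept.

# Synthetic task schedules and behaviour

`generate_schedule()` emulates the multi-attribute task: options are
(magnitude, probability) pairs with magnitudes $\{2, \ldots, 12\}$ and
probabilities $\{12.5\%, \ldots, 87.5\%\}$, 150 two-option plus 150
distractor trials randomly interleaved, with every two-option (HV, LV)
configuration matched attribute-for-attribute to exactly one distractor
trial.  Matching is exact on the attribute pairs, not merely on EV,
which is the stronger reading of "matched configurations".  The relative
distractor value is controlled directly: each distractor trial draws a
uniform $D-HV$ offset, symmetric within the room the EV range leaves
around that trial's HV, and snaps it to the nearest attainable EV.
This spans the decision space (including $D < LV$ and $D > HV$) while
keeping the relative distractor value conditionally centred given the
pair, so it is uncorrelated -- through second *and* third moments --
with the difficulty regressor.  That last property matters: asymmetric
or value-dependent distractor placement induces a small but systematic
finite-sample bias in the logistic interaction coefficient, which a
208-participant group test can mistake for an artefactual distractor
effect.  Loss schedules are gain schedules with all outcomes negated
(swapping the HV/LV roles), mirroring how the loss session re-used the
gain session's trials.  Loss schedules negate all EVs.  Catch trials are a 15% flag
that never enters analyses.  The exact distractor schedule of the
original experiments is not printed anywhere, so synthetic schedules
guarantee coverage, not replication of the original trial lists.

`generate_behaviour()` produces choices either from an accumulator
model (EVs affinely rescaled into model value units by `value_scale`;
the default 0.5 places task EVs in the range spanned by the
decision-space grid, keeping the standard drift/noise values meaningful)
or from a logistic coefficient generator with an optional
distractor-lapse rate that produces attentional-capture choices.  Loss
schedules are not simulated by the accumulator models: modelling choices
among losses would require committing to an avoidance parameterisation
the gain-trial models do not constrain.

What the synthetic data do *not* emulate: sequential effects, learning
or drift in attribute weighting, RT deadlines coupled to attention, and
the original experiments' actual distractor schedules.  Passing
recovery tests on these data therefore demonstrates correctness of the
pipeline, not that real participants satisfy the generators'
assumptions.

# Model fitting and comparison

The original analyses fitted each model's $d$ and $\sigma$ per
participant with a variational-Laplace toolbox whose likelihood is not
reproducible from the text, so this package substitutes a documented
simulation-based likelihood: for every trial, `n_sim` forward runs are
binned into a joint choice-by-RT histogram (50 ms bins over
$(T_{nd}, T_{nd} + 6]$ plus an undecided cell), smoothed along RT
within each choice by a Gaussian kernel (SD 0.1 s) that preserves each
choice's probability mass, floored at $\varepsilon = 10^{-6}$.
Common-random-number seeding makes the surface deterministic, which the
derivative-free optimiser requires.  Distractor trials use the full
model; two-option trials its reduction without the D pool.  Because a trial's
likelihood only queries the RT bin of its own observation, each trial's
simulation is capped just past its observed RT — an exact shortcut that
leaves every queried probability unchanged.

`fit_accumulator()` follows a two-stage scheme: a coarse screen over
starting values ($d \in \{0.01, 0.1, 1, 10\} \times \sigma \in \{0.1,
1\}$, crossed per route for the dual model, plus the model's canonical
operating point) at a quarter of the simulation budget, then
Nelder--Mead refinement on log/logit-transformed parameters within the
bounds $d \in [10^{-3}, 10^2]$, $\sigma \in [10^{-2}, 10]$,
$f \in [0, 1]$, $T_{nd} \in [0.1, 1]$ s.  Variants hold $f = 0.5$ and
$T_{nd} = 0.3$ fixed, free $f$, or free both.  The approximate log
model evidence is the maximised log-likelihood minus a Bayesian
information penalty $\tfrac{k}{2}\ln n$; absolute evidence values are
not comparable to variational free energies, so model comparison is
validated by parameter- and model-recovery rather than by matching
evidence values.

`bms()` implements the variational random-effects model-selection
scheme of Stephan et al. (2009): a Dirichlet prior over population
model frequencies, alternating responsibility/pseudo-count updates, and
exceedance probabilities by Monte-Carlo sampling of the posterior
Dirichlet.

Problem sizes for the recovery analyses in the test suite were chosen
as the smallest that give unambiguous outcomes: parameter recovery uses
one participant with 300 trials (fitting simulations at 5 ms steps,
`n_sim = 200`); model recovery uses cohorts of synthetic participants
with 300 trials each, fitted at 20 ms steps with `n_sim = 60`, which
preserves model rank order while keeping the confusion analysis
tractable on a single CPU.

# Artefact-control simulations

`run_artefact_simulation()` regenerates choices under restricted
generators and re-runs the standard accuracy GLM to check that the
difficulty-dependent distractor interaction cannot be manufactured by
the pipeline: simulations 1 and 2 carry only the difficulty effect
(extracted from a full or a difficulty-only source fit, respectively)
and should reject at the nominal rate; simulation 3 re-injects all
three effects as a positive control.  Hypothetical participants reuse
the source participants' schedules.

# Gaze analysis

Fixations are maximal runs of consecutive valid samples inside one
300-by-300-pixel AOI lasting more than 50 ms; invalid samples break
runs (a bridge-gap mode that tolerates short invalid gaps is available
but off by default, since the original definition is not stated).
Trials below 85% sample validity are excluded (70% in relaxed mode).
Only decision-phase samples are analysed.  Although the stated geometry
(eight positions 291 px from centre, 45 degrees apart, 300 px boxes)
makes adjacent AOIs overlap slightly, hits are resolved to the nearest
stimulus centre.  The synthetic gaze generator is a Markov chain over
the options with configurable dwell, value attraction, a
distractor-value-dependent D-to-HV transition bias, and validity
dropout; it exists to exercise the feature extraction and the
fixation/shift regressions end to end, not to model oculomotor control.

# Known limitations

* The simulation-based likelihood is approximate; evidence differences
  of order one nat are within its resolution, and the BIC-style penalty
  is a surrogate for a proper marginal likelihood.
* Loss-trial choice behaviour is generated but never modelled
  mechanistically.
* The biophysical attractor network that motivates the mutual
  inhibition model, collapsing bounds, and urgency signals are out of
  scope.
* Synthetic schedules cover the designed value ranges but are not the
  original trial lists; analyses of the deposited empirical data sets
  are supported through the CSV/alias loaders.

# Reproducing the headline numbers

`scripts/acceptance.R` simulates the three distractor-aware models over
the full grid (500 iterations per cell), fits the accuracy GLM per
simulated participant, runs the hard/easy stepwise analysis on the dual
cohort, and writes the resulting accuracies and group-mean coefficients
to JSON.  See the README for the exact invocation.
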