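---
title: "Model-integrated virtual bioequivalence for long-acting injectable paliperidone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-integrated virtual bioequivalence for long-acting injectable paliperidone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbesim)
```

## The problem

Long-acting injectable (LAI) suspensions of paliperidone palmitate release
drug over weeks to months. Demonstrating bioequivalence (BE) of a generic
LAI against the reference product with a conventional clinical trial is
close to infeasible: inter-subject variability in exposure is around 50%,
a single dosing interval lasts three months, and a parallel trial would
need hundreds of subjects followed for more than a year. Virtual
bioequivalence (VBE) replaces most of that burden with simulation: a
population pharmacokinetic (PK) model, validated for the reference
formulation, is recalibrated with a small ("abbreviated") clinical trial
and then used to simulate the large trials that cannot be run.

`vbesim` implements the full chain: the structural PK model, the
hierarchical population layer, virtual-trial generation, Bayesian
recalibration of the formulation difference, and two BE decision
workflows -

* **Workflow A** (partly Bayesian, data-based): simulate one
  realistically large parallel trial, compute non-compartmental (NCA)
  Cmax and partial AUC per subject, and apply the two one-sided tests
  (TOST): BE is declared when the 90% confidence interval of the
  test/reference geometric-mean ratio (GMR) lies inside [0.8, 1.25] for
  both metrics.
* **Workflow B** (fully Bayesian, model-integrated): propagate the
  posterior of the formulation difference through many simulated trials
  to estimate the joint posterior-predictive distribution of the Cmax and
  AUC GMRs, and declare BE when
  P(both ratios in [0.8, 1.25]) is at least 0.95.

## Structural model

Two depot models are solved jointly, feeding one central compartment with
linear clearance (time in days, amounts in mg eq., volumes in L,
concentrations in ng/mL):

* **PP1M (1-month product).** After an injection of `Dose1`, a fraction
  `f1` is released at the constant rate `f1 * Dose1 / tl1` until
  `tl1` days after the injection (zero-order phase); the remaining
  `(1 - f1) * Dose1` then enters a first-order depot released with rate
  constant `ka1`.
* **PP3M (3-month product).** A fraction `f3` of each dose enters a rapid
  depot with Michaelis-Menten release
  (`kar3_max * Q / (kar3_50 + Q)`), the rest a slow depot with Hills
  release (`kas3_max * Q^gamma / (kas3_50^gamma + Q^gamma)`).

Injections accumulate in the same depots. Subjects may carry a pre-trial
body burden `Qc0` in the central compartment. Two auxiliary states are
integrated alongside: the running integral of concentration (so partial
AUC is a by-product of the solve, not a quadrature of an output grid) and
the cumulative eliminated amount (so exact mass balance is checkable at
every output time).

The zero-order phase is implemented by event-scheduled rate switching:
the full PP1M dose enters the fast depot at injection, the constant rate
is active for exactly `tl1` days, and the unreleased `(1 - f1)` share is
transferred to the first-order depot when the window closes. Overlapping
windows from successive injections simply add their rates. This
reproduces the stated initial and terminal depot conditions exactly and
keeps mass balance to solver accuracy.

## Population layer and the formulation shift

Subject parameters `ka1`, `kar3_50`, `kas3_max`, `kas3_50`, `CL`, `V`
and the initial burden `Qc0` are lognormal around geometric means;
`kar3_max` and `gamma` are shared constants. The fractions `f1`, `f3`
use a positive lognormal latent `kappa` mapped to (0, 1).

Two latent transforms are implemented and switchable, because the
published hierarchy composes an odds-scale latent with a logistic
inverse, which is internally inconsistent:

* `odds_ratio` (default): `theta = kappa / (1 + kappa)`. The configured
  location is then exactly the median fraction.
* `paper_logistic`: `theta = 1 / (1 + exp(-kappa))` applied to the
  odds-scale latent. Because `kappa > 0`, every fraction is forced into
  (0.5, 1).

The default was chosen on structural grounds: under `paper_logistic`
more than half of every PP3M dose is routed through the rapid depot
regardless of configuration, and the rapid-depot maximum rate then
dominates Cmax sensitivity. That contradicts the well-established
behaviour of this model family, in which the slow-depot maximum release
rate (`kas3_max`) is the most influential release parameter on both Cmax
and partial AUC at steady state — the behaviour the `odds_ratio` default
restores (see `sensitivity_ranking()`).

A test formulation differs from the reference by a six-component
multiplicative shift `delta` on the geometric means of the drug-release
parameters, in the order (`f3`, `kas3_max`, `kar3_max`, `kas3_50`,
`kar3_50`, `gamma`); for `f3` the shift acts on the latent kappa's
geometric mean. Random-effect covariances are set to zero (only the
variances are used).

## Default parameter profile

The structural values of the published paliperidone model are not
printed in the main text of the source literature, so the package ships
a documented placeholder profile (`default_population()`), calibrated
once to the qualitative regime that model family exhibits, and not
revisited:

| parameter | value | role |
|---|---|---|
| `f1`, `f3` | 0.15 | median fast-release fractions |
| `tl1` | 7 d | zero-order window |
| `ka1` | 0.02 /d | PP1M first-order release (t1/2 ~ 35 d) |
| `kar3_max`, `kar3_50` | 8 mg/d, 100 mg | rapid PP3M depot |
| `kas3_max`, `kas3_50`, `gamma` | 5 mg/d, 300 mg, 1.3 | slow PP3M depot |
| `CL`, `V` | 120 L/d, 400 L | disposition |
| `Qc0` | GM 30 mg eq., GSD 1.5 | pre-trial burden |
| log-SDs | 0.30 (0.25 for `kas3_max`, 0.50 for `CL`) | inter-subject variability |
| residual | log-SD 0.2 | measurement/model error |

This yields average concentrations near 40-55 ng/mL under 525 mg eq.
every 13 weeks, months-long release, exposure CVs of roughly 50-55%
across subjects (the regime the workflows are meant to stress), a few
percent exposure change for a 5% change in `kas3_max`, and `kas3_max`
ranked first in the sensitivity analysis. These values are configuration,
not ground truth: a user with the published supplementary estimates
should place them in a YAML profile (see `default_run_config()`).

## Trial simulation

The standard regimen is four monthly PP1M injections of 150 mg eq.
(days 0, 28, 56, 84) followed by four PP3M injections of 525 mg eq.
every 13 weeks (days 112, 203, 294, 385). Two published sparse sampling
schedules are available: weeks 54, 55, 57, 59, 63 (default) and weeks
54, 55, 57, 61, 65 (the 11-week variant); the sources print both and do
not disambiguate which produced which figure. NCA metrics use the
sampling span as the analysis interval; model-integrated metrics use the
last dosing period (days 385-476), with Cmax searched on a uniform
100-point grid (refining to 10,000 points moves Cmax by well under
0.5% at steady state, which the tests verify).

Measured concentrations are lognormal around the model prediction with
fixed log-variance. The abbreviated design (25/arm, 5 samples) yields
the canonical 250-record calibration set; the large design uses 130/arm.

## Recalibration of the formulation difference

Only the second shift component, `delta2` on `kas3_max`, is estimated;
the other five are fixed at 1, and the population locations, variances
and residual variance stay at their configured central values. The
sampler is blocked random-walk Metropolis-Hastings on the latent log
scale: each subject's nine parameters (`f1`, `f3`, `ka1`, `kar3_50`,
`kas3_max`, `kas3_50`, `CL`, `V`, `Qc0`) form one joint proposal block
(one ODE solve per proposal), and `delta2` has its own block, which only
touches the test-arm population terms and its lognormal prior (GM 1,
GSD 2). For the 25-per-arm design this is 451 parameters. Proposal
scales adapt toward 20-40% acceptance during burn-in and are frozen
afterwards, so the retained draws target the exact posterior.
Convergence is monitored with the Gelman-Rubin potential scale reduction
factor (R-hat < 1.1 taken as sufficient). The default run is 4 chains of
10,000 iterations with 2,500 discarded.

Correctness is checked three ways in the test suite: a reduced conjugate
route (`sample_subjects = FALSE`) against the closed-form normal-normal
posterior, a near-noise-free likelihood that must recover subject
clearances, and seeded recovery experiments in which the 95% credibility
interval must cover the generating `delta2`.

## Decision workflows, power and safe space

`power_type1()` estimates operating characteristics of workflow A by
repeated simulation. Boundary placements multiply the test-arm
concentrations by a limit so the true GMR of every metric sits exactly
on it. A note on what to expect there: with a pooled TOST at one-sided
`alpha = 0.05`, the per-metric pass probability at a true GMR exactly on
a limit is the t-test level itself (about 5%) whenever the opposite
constraint does not bind; requiring both correlated metrics to pass
brings the joint rate to roughly 4% under the default variability. An
observed rate materially below 2.5% per side would instead indicate a
stricter nominal level (a 95% CI) or a boundary placed outside the
limits.

`safe_space_A()` samples all six delta components uniformly (default
U[0.5, 2]), runs a full trial per draw and records the TOST verdict -
a fuzzy map, because single-trial decisions near the limits are
power-limited. `safe_space_B()` fixes delta on a grid over the two most
critical parameters (`f3`, `kas3_max` shifts), averages the noise-free
model-integrated ratios over many trials, and declares a point safe when
both averaged ratios lie inside the limits; this is the crisp,
uncertainty-free boundary, and a probabilistic rule variant is available
for boundary-uncertainty studies. `safe_space_boundary_B()` refines the
crisp boundary by bisection (tolerance 0.01 in delta space). Because the
uniform safe-space sampling multiplies `gamma` by values down to 0.5,
the subject-parameter domain accepts any positive Hills exponent; the
default profile keeps `gamma` above 1.

## Numerical choices

* Integrator: explicit Dormand-Prince 5(4) with FSAL and step control,
  hard stops at every injection and zero-order window boundary (the
  right-hand side is discontinuous there), written in C++ for the
  sampler's benefit; `deSolve` serves as an independent oracle in the
  test suite (agreement to 1e-6 relative).
* Tolerances: `rtol = 1e-8`, `atol = 1e-10` for user-facing profile
  simulation; the MCMC likelihood uses `rtol = 1e-5`, `atol = 1e-7`,
  a deliberate trade — the induced relative solution error (~1e-5) is
  four orders of magnitude below the residual SD (0.2), and the looser
  tolerance roughly triples sampling throughput.
* Negative states: values in [-1e-9, 0] are clamped to zero; anything
  below raises an error naming the offending state and time.
* Seeding: a single master seed; trial- and stage-level streams are
  derived deterministically (`derive_seed()`), all below 2^31.
* Ties and degenerate inputs: TOST refuses two constant arms; NCA
  requires at least two observations in the interval; posterior
  summaries require at least 100 draws.

## What the synthetic generator does and does not emulate

The generator reproduces the features that drive BE operating
characteristics: lognormal inter-subject variability with ~50-55%
exposure CV, lognormal residual error, sparse sampling, depot
accumulation across eight injections, and a pre-trial body burden. It
does not emulate covariate effects (none were implementable from the
published model), random-effect correlations, inter-occasion
variability, dropout, or the unreported per-subject PP1M dose
adjustments of the original trials (folded into residual error).
Passing tests therefore demonstrate the statistical machinery under a
faithful variability regime, not predictive accuracy for any real
formulation; that would require the original structural estimates and,
ideally, in vitro release data.

## Problem sizes used by the automated checks

The test suite runs reduced but honest versions of each experiment:
recovery uses five seeded replicates of a 100-per-arm trial with
4 x 2,000 MCMC iterations; power and type-I use 100 trials of 130
subjects per arm; workflow-B calibration uses 200 trials of 200
subjects per arm; the safe-space consistency check uses a 5 x 5 grid
with 50 trials per point. The acceptance script
(`scripts/acceptance.R`) recomputes the type-I error and power numbers
from scratch at the same sizes.

## Known limitations

* The default profile is a calibrated placeholder; quantitative claims
  tied to the original supplementary estimates (for example the
  published posterior-predictive exceedance probabilities) are not
  reproducible without them, and the corresponding acceptance check is
  expected to fail until a user supplies those values.
* Only parallel designs are simulated; no replicate or cross-over
  machinery, no reference-scaled average BE.
* The sampler is a random-walk Metropolis scheme; it is exact but mixes
  more slowly than gradient-based samplers for the 451-parameter
  problem, hence the long default chains.
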