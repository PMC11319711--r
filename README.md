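# vbesim

Model-integrated **virtual bioequivalence (VBE)** assessment for
long-acting injectable (LAI) paliperidone palmitate formulations.

Comparing a generic LAI suspension against its reference product with a
conventional trial is close to infeasible: exposure varies ~50% between
subjects, one dosing interval lasts three months, and a parallel trial
would need hundreds of subjects followed for over a year. `vbesim`
implements the simulation-based alternative end to end:

* a joint structural PK model of the 1-month (PP1M: zero-order burst
  plus first-order depot) and 3-month (PP3M: rapid Michaelis–Menten plus
  slow Hills saturable depots) products, solved by a compiled
  event-aware adaptive integrator with exact mass balance;
* a hierarchical population layer — lognormal inter-subject variability,
  latent-scale fractions, lognormal residual error — and a six-component
  multiplicative formulation-shift vector δ on the drug-release
  parameter means (test vs. reference), δ₂ being the shift on the
  slow-depot maximum release rate `kas3_max`;
* virtual parallel-trial simulation (abbreviated 25/arm and large
  130/arm designs, sparse sampling over the last dosing period);
* Bayesian recalibration of δ₂ from abbreviated-trial concentrations by
  blocked Metropolis–Hastings (subject-level parameters jointly with δ₂;
  Gelman–Rubin diagnostics);
* two BE decision workflows:
  * **A (data-based):** per-subject NCA Cmax and partial AUC, then the
    two one-sided tests (TOST) — BE iff the 90% CI of the
    test/reference geometric-mean ratio lies in [0.8, 1.25] for both
    metrics;
  * **B (model-integrated):** the posterior-predictive distribution of
    the Cmax and AUC geometric-mean ratios over many noise-free trials —
    BE iff P(both ratios ∈ [0.8, 1.25]) ≥ 0.95;
* power / type-I error simulation, local sensitivity ranking of the six
  release parameters, and safe-space maps (fuzzy TOST-based and crisp
  model-based, with bisection boundary refinement).

The methods vignette (`vignettes/vbe-methods.Rmd`) documents the model,
the default parameter profile (a calibrated placeholder for the
unpublished structural estimates) and every numerical choice.

## Worked example

A full workflow: simulate an abbreviated trial whose test arm truly has
a 5% larger `kas3_max` (δ₂ = 1.05), recalibrate δ₂ from those 250
observations, then decide BE both ways.

```r
library(vbesim)

pop_true <- default_population(delta = c(1, 1.05, 1, 1, 1, 1))
trial <- simulate_trial(abbreviated_trial_design(seed = 42), pop_true)
summ <- summarize_trial(nca_by_subject(trial))
be_workflow_A(trial)

fit <- run_mcmc(mcmc_config(n_chains = 4, n_iter = 2000, n_burnin = 1000,
                            seed = 43),
                trial, default_population())
fit

set.seed(44)
ratios <- posterior_predictive_ratios(fit$delta2, default_population(),
                                      n_trials = 200, n_per_arm = 200)
be_workflow_B(ratios)
```

Output (abridged):

```
abbreviated trial: GMR Cmax 0.92, GMR AUC 0.91, CV Cmax 71%
Workflow A (data-based TOST) BE decision
  Cmax: TOST: GMR 0.9236, 90% CI [0.6702, 1.2727], limits [0.8, 1.25] -> FAIL
  AUC : TOST: GMR 0.9073, 90% CI [0.6702, 1.2283], limits [0.8, 1.25] -> FAIL
  overall: not bioequivalent
MCMC result: 4 chains x 1000 retained draws, 451 parameters
  delta2: GM 0.942, GSD 1.146, 95% CrI [0.695, 1.189]
Workflow B (posterior predictive) BE decision
  P(both ratios in [0.8, 1.25]) = 0.995 (threshold 0.95)
  overall: bioequivalent
```

Reading it: the truly near-equivalent formulations (δ₂ = 1.05) fail the
data-based TOST — 25 subjects per arm with ~50–70% exposure CV give a
confidence interval far wider than the BE limits, so the abbreviated
trial alone is inconclusive. The recalibration pools those same 250
observations with the prior and localizes δ₂ (CrI 0.70–1.19, covering
the true 1.05), and workflow B — which averages over 200 large virtual
trials instead of gambling on one — correctly declares bioequivalence
with P(BE) = 0.995. Note that the δ₂ point estimate (0.94 here) is at
the mercy of which random abbreviated trial was drawn; that sampling
noise, not the method, dominates small-trial recalibration.

## Command line

A thin CLI over the same functions ships in `inst/cli/vbe.R`:

```sh
Rscript inst/cli/vbe.R init-config --out cfg
Rscript inst/cli/vbe.R simulate --design abbreviated --config cfg/vbe_config.yaml --out run
Rscript inst/cli/vbe.R recalibrate --input run/abbreviated_trial.csv --config cfg/vbe_config.yaml --out run
Rscript inst/cli/vbe.R assess --mode B --input run/recalibration_summary.json --config cfg/vbe_config.yaml --out run
Rscript inst/cli/vbe.R power --placement boundary_upper --out run
```

Every stage writes CSV/JSON results plus a provenance manifest (seed,
configuration hash); reruns from the same configuration are
byte-identical.

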