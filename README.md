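# mipdtrial

Simulation of clinical trials for model-informed precision dosing (MIPD),
with warfarin anticoagulation as the use case.

Warfarin doses that keep one patient's INR (international normalised ratio)
at the 2.5 target can push another far beyond the therapeutic range [2, 3]:
the dose requirement varies several-fold with VKORC1 and CYP2C9 genotype,
age, and unexplained inter-individual variability. MIPD methods individualise
dosing from covariates and monitoring data, but comparing them in real trials
is prohibitively expensive. This package simulates the entire programme
instead, for anyone developing or benchmarking dosing algorithms.

## The clinical trial model

Virtual patients and their noisy monitoring data come from a five-component
clinical trial (CT) model:

1. **Mechanistic model** — reduced warfarin PKPD: one-compartment PK with
   first-order absorption (`da_d/dt = −k_a a_d + r(t)`,
   `da_c/dt = k_a a_d − k_e a_c`, `C = a_c/V`), an inhibitory Hill effect
   `E(C) = 1 − C^γ/(EC50^γ + C^γ)` driving a transit chain of clotting
   activity (`k_tr = n/MTT`), and readout
   `INR = INR_0 + INR_max · max(0, 1 − A_n)^λ`. Nonlinear, with a multi-day
   response delay.
2. **Population model** — mixed effects: VKORC1 scales EC50, CYP2C9 and age
   scale `k_e`, lognormal random effects `ψ_i = ψ_typ · exp(ω z)` on
   `k_e`, EC50, MTT and V.
3. **Inter-occasion model** — a fresh `η ~ N(1, 0.1²)` multiplier on the
   vitamin K input each day.
4. **Execution model** — exponential delays (mean 30 min) on every nominal
   dose and measurement time; coincident events share one delay.
5. **Measurement model** — lognormal noise with the model output as median
   and scale σ = 0.1 (~10 % error).

On top of this sit the pre-MIPD trial protocols (phase I single-dose PK,
N = 60; phase II induction + physician heuristic `d_j = d_{j−1} y*/y_j`,
N = 100; phase III maintenance equilibration, N = 1000), and three dosing
agents for the 19-day MIPD trial:

* **Regression** — a 1024-wide feed-forward network predicting the
  maintenance dose from covariates and target INR (static policy);
* **Deep RL** — a Double-DQN over a 58-dose grid, state = latest INR +
  covariates, trained online against a PKPD treatment-response emulator;
* **Bayesian PKPD** — a hierarchical Metropolis-within-Gibbs fit of the PKPD
  model to phase I–III data, per-patient MAP individualisation from
  monitoring data, and CMA-ES optimisation of the remaining daily doses.

Outcomes are summarised per patient as maintenance INR (last day), peak INR,
and time in therapeutic range (TTR), plus the cohort success rate.

## A worked example

```r
library(mipdtrial)

cfg <- ct_config()                                   # the CT model defaults
phase3 <- run_phase3(cfg, n = 300, seed = 42)        # pre-MIPD trial data
model <- train_regression(phase3, epochs = 60, seed = 1)

predict_maintenance_dose(model, covariate_profile("*1*1", "GG", 65), 2.5)
#> [1] 5.5
predict_maintenance_dose(model, covariate_profile("*1*1", "AA", 65), 2.5)
#> [1] 3

cohort <- sample_cohort(cfg$population, cfg$demo, 30, seed = 7)
trial <- run_mipd_trial(cfg, regression_agent(model), cohort, seed = 8)
summarise_trial(trial, therapeutic_range(2, 3, 2.5))
#> <trial_outcome: 30 patients, success rate 23.3%, median TTR 26%, max peak INR 9.23>
```

The predicted doses order the way warfarin pharmacology says they should
(sensitive VKORC1 AA patients get ~half the GG dose), and the static
covariate-only agent lands a minority of patients in range — feedback-based
agents (`rl_agent()`, `pkpd_agent()`) do better because they can react to
the variability that covariates do not explain. The methods vignette
(`vignettes/mipd-trial-simulation.Rmd`) documents every model component,
default and numerical choice.

## Command line

A thin CLI over the same functions lives at `inst/cli/mipdtrial.R`:

```sh
Rscript inst/cli/mipdtrial.R simulate-phase3 --seed 1 --out phase3/
Rscript inst/cli/mipdtrial.R train-regression --phase3 phase3/ --out model.json
Rscript inst/cli/mipdtrial.R run-mipd-trial --agent regression --model model.json --n 100 --seed 2 --out trial/
Rscript inst/cli/mipdtrial.R report --trial trial/ --range 2:3 --out summary.json
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
simulates the three pre-MIPD trial phases, trains the regression agent on
the phase III data, runs a seeded MIPD trial against the zero-dose stub, and
prints the outcome metrics — then writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
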