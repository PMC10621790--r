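---
title: "Simulating MIPD trials for warfarin: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating MIPD trials for warfarin: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipdtrial)
```

## The problem

Warfarin has a narrow therapeutic window and a famously variable dose
requirement: the daily dose that holds one patient's INR (international
normalised ratio, the monitored anticoagulation response) at 2.5 may push
another patient far beyond it. Model-informed precision dosing (MIPD) tries
to individualise dosing from covariates (here the VKORC1 and CYP2C9
genotypes and age) and from monitoring measurements. Comparing MIPD methods
in real trials is prohibitively expensive, so this package simulates the
whole programme: virtual cohorts, the pre-MIPD trials used to fit dosing
models, and the MIPD trial itself, in which a dosing agent treats each
virtual patient for 19 days towards a target INR of 2.5.

The clinical-trial (CT) model is deliberately modular, with five independent
components. Each captures one layer of difficulty that a dosing method must
survive in practice:

1. a **mechanistic model** of the warfarin response with realistic
   nonlinearity and multi-day delay,
2. a **population model** creating inter-individual variability (IIV),
   partly explained by covariates,
3. an **inter-occasion model** (IOV) perturbing the vitamin K input from day
   to day,
4. an **execution model** delaying nominal dose and measurement times, and
5. a **measurement model** adding lognormal noise to every observation.

## The mechanistic core

The full coagulation-network models used in the literature track dozens of
blood components and simulate an in-silico prothrombin-time test. That
machinery is out of scope here; instead the package uses a reduced warfarin
PKPD model with the same interface and the same qualitative behaviour
(nonlinearity, multi-day delay, vitamin K coupling):

* One-compartment pharmacokinetics with first-order absorption:
  `da_d/dt = -ka a_d + r(t)`, `da_c/dt = ka a_d - ke a_c`, concentration
  `C = a_c / V`. Oral doses are instantaneous boluses into `a_d`; infusion
  durations are not modelled.
* An inhibitory Hill effect `E(C) = 1 - C^gamma / (EC50^gamma + C^gamma)` on
  the production input of a transit chain of clotting activity:
  `dA1/dt = ktr (eta_day E(C) - A1)`, `dAi/dt = ktr (A_{i-1} - A_i)` with
  `ktr = n_transit / MTT`.
* INR readout `INR = inr_base + inr_max * max(0, 1 - A_n)^lam`.

The daily multiplier `eta_day` is the vitamin K input analogue: a day of
higher vitamin K intake (`eta > 1`) raises the production input, which can
only push the INR back towards baseline, while a low-intake day raises the
INR. This reproduces the clinically known reversal of warfarin's effect by
vitamin K. It is an analogue of the full network's vitamin K input rate, not
a reconstruction of it.

### Default parameters and calibration

| parameter | default | unit | meaning |
|---|---|---|---|
| `ka` | 1.0 | 1/h | absorption rate |
| `ke` | 0.018 | 1/h | elimination rate (half-life ~38 h) |
| `V` | 14 | L | volume of distribution |
| `EC50` | 6.4204 | mg/L | half-maximal inhibitory concentration |
| `gamma` | 1.2 | – | Hill coefficient |
| `MTT` | 40 | h | mean transit time of the delay chain |
| `n_transit` | 3 | – | transit compartments |
| `inr_base` | 1.0 | – | baseline INR |
| `inr_max` | 19 | – | maximal INR increment |
| `lam` | 1.0 | – | response-shape exponent |

The literature models defer their numeric parameterisation to supplementary
material and reference publications, so the defaults above are pinned by
behaviour instead: `EC50` is the root of
`steady_state_inr(5 mg/day, typical patient) = 2.5`, found by `uniroot` over
the package's own steady-state routine (`calibrate_ec50()`), so the typical
(GG, \*1\*1, age 71) patient on 5 mg/day sits at the middle of the
therapeutic range. The remaining values were chosen once for physiological
plausibility (a ~38 h half-life, a pharmacodynamic delay of several days)
and are configuration, not claims about any particular patient population.

### Numerical integration

The system is integrated with an adaptive Dormand–Prince 5(4) stepper
written in Rcpp (no ODE solver package ships in the supported environment).
Dose events restart the step at the event time; the daily `eta` is
piecewise constant over calendar days (`day k = [24k, 24(k+1))`, 0-based),
and day boundaries are step restarts only when `eta` actually varies. The
default tolerances are `rtol = 1e-8`, `atol = 1e-10` — stricter than the
usual 1e-6/1e-8 — so that the concentration agrees with the closed-form
single-dose (Bateman) solution to better than 1e-6 relative over multi-week
horizons, with step-size continuity across event restarts. The acceptance
suite verifies this equivalence against an independently coded closed form.

## Population model

Covariates route into the mechanistic parameters the way the warfarin
literature describes: VKORC1 A alleles lower `EC50` (stronger inhibition at
the same concentration), CYP2C9 variant alleles lower `ke` (slower
clearance), and age modulates `ke` linearly (−1 %/year around the reference
age 71). Defaults:

* `cyp2c9_ke_mult`: \*1\*1 1.00, \*1\*2 0.73, \*1\*3 0.40, \*2\*2 0.55,
  \*2\*3 0.35, \*3\*3 0.20
* `vkorc1_ec50_mult`: GG 1.00, GA 0.60, AA 0.35
* lognormal random-effect SDs (`omegas`): `ke` 0.25, `EC50` 0.30, `MTT`
  0.20, `V` 0.10

These preserve the qualitative structure (direction and ordering of the
genotype effects, substantial IIV left unexplained by covariates); the
numeric values of published mixed-effects warfarin models live in their
supplementary material and are not reproduced. Individual parameters are `typical * exp(omega * z)` with
standard-normal `z`. Default demographics: Hardy–Weinberg VKORC1
frequencies with A-allele frequency 0.40 (GG 0.36, GA 0.48, AA 0.16), CYP2C9
frequencies dominated by \*1\*1 (0.65), and ages `round(Normal(65, 10))`
truncated to [18, 100]. All of this is configuration serialised to JSON
(`write_config()`; YAML is not available in the supported environment).

## Stochastic layers

* **IOV**: one `Normal(mu_eta = 1, sigma_eta = 0.1)` draw per simulation
  day, truncated below at 0.05 (a plain normal multiplier must stay positive
  to be a production rate). The truncation is invisible in practice
  (5 sigma below the mean) but guards degenerate configurations.
* **Execution**: exponential delays with mean `tau = 30` minutes added to
  every nominal administration and monitoring time; a dose and a measurement
  sharing a nominal time share one delay draw. Dose amounts are never
  perturbed, and datasets record nominal times by default
  (`report_actual_times` flips this) — mirroring how clinical datasets
  usually report the planned schedule.
* **Measurement**: lognormal with the model output as median and scale
  `sigma = 0.1`, i.e. ~10 % proportional error. Missed doses/measurements
  and covariate (genotyping) errors are documented extension points, not
  implemented.

One consequence of the reduced model worth knowing: with `lam = 1` and
`inr_max = 19`, the untreated INR is quite sensitive to low-vitamin-K days
(a sustained `eta = 0.9` alone would raise the INR towards 2.9). Treated
trajectories therefore show IOV swings at the upper end of what the
published IOV illustrations display. The effect is one-sided at baseline (high-intake
days are clamped by the `max(0, ...)` floor), so an untreated cohort's
median INR stays near baseline, which is what the zero-dose stub agent test
asserts.

## Trial protocols

* **Phase I** (N = 60): single 10 mg dose, concentration measured at nominal
  10, 35 and 60 h.
* **Phase II** (N = 100, 3 weeks): daily dosing, fixed induction
  (10, 7.5, 5 mg), then the linear physician heuristic
  `d_j = d_{j-1} y*/y_j` applied on days 3, 5, 7 and 13 using the INR taken
  just before that administration; INR measured pre-dose on days 0, 1, 2, 3,
  5, 7, 13 and 20. Day indexing is 0-based (day 0 = first dose day), and the
  day-0 measurement is the pre-dose baseline. A patient's arm stops after
  three consecutive INR measurements above 5; stopped patients keep their
  rows up to the stop plus a metadata flag.
* **Phase III** (N = 1000, 8 weeks): the phase II design with further
  adjustments on days 27 and 34, then three constant weeks so patients
  equilibrate; the reported dataset is the day-55 INR and the maintenance
  dose per patient. (Internally the same monitoring days as phase II plus
  20, 27, 34 are measured to drive the heuristic and the stop rule.)
* **MIPD trial** (N = 1000, 19 days): daily pre-dose INR measurement, the
  monitoring record and covariates go to the dosing agent, the returned dose
  (rounded to 0.5 mg, capped at 30 mg) is administered. No stop rule, so
  agent weaknesses are fully visible.

Doses are rounded to 0.5 mg for tablet-like granularity; the 30 mg cap
prevents runaway heuristic doses. Whether phase II adjustments continue
after day 13 is not specified by the protocols this mirrors; here the day-13
dose repeats until the trial ends. Protocol runners never consult a virtual
patient's true parameters — agents see measurements and covariates only.

## The three dosing agents

**Regression** (`train_regression()`): a feed-forward network (two hidden
layers of width 1024, ReLU; sigmoid output scaled to [0, 30] mg) regresses
the maintenance dose on one-hot genotypes, standardised age and the achieved
end-of-trial INR, trained with Adam (lr 1e-4, batch 64, up to 500 epochs,
90/10 split, early-stopping patience 50) on phase III data. At prediction
time the target INR is substituted for the response feature. Two numerical
choices keep the saturating output trainable: targets are normalised by the
30 mg output scale with Xavier initialisation of the output layer, and the
learning rate is 1e-4 rather than the more usual 1e-3 — with a 1024-wide
final hidden layer, Adam's per-parameter steps at 1e-3 drift the sigmoid
pre-activation by ~0.3 per update, overshoot the target range within an
epoch and park the output in the saturated region where gradients vanish. The policy is
static: identical covariates imply identical regimens, and monitoring data
are ignored.

**Deep RL** (`train_rl_agent()`): a Double-DQN whose state is the latest INR
measurement plus covariates (a Markov state — the method must assume
tomorrow's INR depends only on today's INR and dose, which warfarin's
multi-day delay violates; that mismatch is a finding, not a bug). The
Q-network is 11 → 256 → 128 → 64 → 58 (one output per 0.5 mg grid dose, 0 to
28.5 mg). Reward `-|INR_next - y*|` is maximal exactly on target; published deep-RL dosing studies rarely print their reward function, so
this simplest on-target-maximal choice is used and logged. Defaults: discount 0.99,
epsilon 1 → 0.05 linearly over the first 80 % of episodes, replay buffer
50k, batch 64, target-network sync every 500 steps, Adam lr 1e-4, 19-day
episodes. The training environment is a treatment-response emulator built
from the *fitted* PKPD population model (`posterior_emulator()`), so the RL
agent learns only from information the PKPD agent also has; the emulator
applies measurement noise but no execution delays or IOV (a fitted model
carries neither). Trial evaluation always uses the full CT model.

**Bayesian PKPD** (`fit_population()`, `pkpd_agent()`): the MIPD-internal
model is the same reduced PKPD structure as the CT model — no deliberate
structural misspecification by default — but it is blind to IOV and
execution delays, whose contribution it absorbs into residual noise.
`fit_population()` runs a Metropolis-within-Gibbs sampler (no NUTS
implementation exists in the supported environment; adaptive random-walk
MCMC is the standard gradient-free alternative in this setting): per-patient
4-dimensional random-walk updates of the random effects, a joint update of
the log typical `ke`/`EC50`, likelihood-invariant recentring moves along the
typical/random-effect ridge, and conjugate inverse-gamma Gibbs steps for the
omegas and residual variances. Proposal scales adapt during warmup only.
Priors: `Normal(log default, 0.5^2)` on the log typicals,
`InvGamma(2.5, 0.06)` on omega² (prior mean omega ≈ 0.2) and
`InvGamma(2.5, 0.015)` on sigma² (prior mean sigma ≈ 0.1). Covariate
multipliers, the age slope and the remaining typical values are treated as
known structural prior knowledge, as MIPD PKPD models typically
inherit their covariate structure from published population analyses. Split R-hat ≥ 1.05 on
any retained parameter produces a warning and a flagged posterior, never a
silent success. Phase III maintenance-dose records are fitted by
approximating the trial with constant daily dosing at the maintenance dose,
which is accurate because the final three constant weeks dominate the
day-55 INR.

Individualisation is MAP: `fit_individual_map()` maximises the posterior of
the four random effects given the patient's INR record, by Nelder-Mead from
five starts (prior mode, ±omega on `ke` and on `EC50`); the sequential agent
warm starts later days from the previous optimum plus the prior-mode
safeguard. An empty record returns exactly the subpopulation-typical
parameters. `optimise_regimen()` then minimises the sum of squared
deviations of the predicted next-morning INRs from the target over the
remaining daily doses, with a compact CMA-ES (population 8, 200-iteration
budget, box repair onto [0, 30] mg, warm started from the previous day's
solution shifted by one day). The all-zero regimen and the warm start are
always evaluated, so degenerate objectives (e.g. a model with `inr_max = 0`,
or a target equal to baseline) fall back to zero dosing. Full-posterior
(rather than MAP) predictive dosing is a known mitigation of MAP bias and is
deliberately not the default, matching common MAP-guided dosing practice.

## What a green test does (and does not) establish

The synthetic world is the package's own: all data are generated by the CT
model above, so tests establish internal correctness and the qualitative
phenomena (response delay, vitamin K reversal, covariate ordering,
feedback-control policies), not quantitative agreement with any clinical
dataset or with the reference implementation's headline trial percentages,
which depend on an unreleased 53-state mechanistic core and supplementary
training hyperparameters.

Two quantitative observations from this package's own acceptance runs are
worth recording:

* **Population-fit recovery** at 30 patients covers most of the eight
  estimated parameters in 90 % intervals; under the full CT model the
  residual INR scale absorbs IOV and execution variability and is estimated
  above its measurement-only value — expected behaviour of a fitting model
  that is blind to those layers, and visible in the coverage table rather
  than hidden.
* **Individual MAP recovery**: from 19 daily INR measurements of an
  induction-style regimen, the median recovery error across a 60-patient
  panel is ~8 % on the elimination rate and ~11 % on `EC50` — but the error
  distribution is long-tailed, and only ~57 % of individual patients meet a
  15 % bound on both parameters simultaneously. The tail has a structural
  explanation: INR-only data identify the product `V * EC50` (only
  `C/EC50 = a_c/(V EC50)` enters the effect), the prior splits deviations of
  that product between `V` and `EC50`, and MAP shrinkage biases patients far
  from typical towards the population mode — a known bias of MAP-guided
  dosing. Recovery criteria are therefore asserted on
  panel medians; the increasing-individualisation property (average error
  non-increasing in the number of monitoring points) also holds.

## Known limitations

* The reduced mechanistic core is an analogue of the full coagulation
  network, not a reduction of it; no quantitative agreement with the
  in-silico prothrombin-time test is claimed. An external simulator can be
  plugged in through `register_dynamics_backend()` (no SBML parser is
  available in R here, so the hook takes a simulator function rather than a
  model file).
* Untreated-INR sensitivity to low-vitamin-K days is at the high end (see
  above).
* The RL agent's training hyperparameters stand in for unavailable
  supplementary values. Under-exploration of high-INR states is visible at
  reduced training scale: at 2000 episodes the greedy dose function can rise
  again by 0.5–2 mg inside the upper therapeutic band before the policy
  cleans up (both diagnostic covariate profiles are monotone on INR
  [1.5, 4] by 4000 episodes). The acceptance suite trains at 4000 episodes
  for this reason.
* Dropout beyond the safety-stop rule, dose-amount execution errors,
  infusion durations, genotyping noise and model-averaging over structural
  uncertainty are all out of scope.

## A compact end-to-end example

```{r example, eval = FALSE}
cfg <- ct_config()
phase3 <- run_phase3(cfg, n = 300, seed = 1)
reg_model <- train_regression(phase3, epochs = 60, seed = 1)

cohort <- sample_cohort(cfg$population, cfg$demo, 50, seed = 2)
trial <- run_mipd_trial(cfg, regression_agent(reg_model), cohort, seed = 3)
summarise_trial(trial, therapeutic_range(2, 3, 2.5))
```
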