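---
title: "A Markov cost-utility model of salvage cryotherapy versus androgen deprivation therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-utility model of salvage cryotherapy versus androgen deprivation therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryocea)
```

## The decision problem

Men whose prostate cancer recurs locally after primary radiotherapy
(radiation-recurrent prostate cancer, RRPC) are most commonly managed with
androgen deprivation therapy (ADT): a palliative, ongoing monthly treatment.
Salvage cryotherapy (SC) is a one-off ablative alternative with a high
upfront cost that can delay — sometimes avoid — the start of ADT by
"resetting the PSA clock". `cryocea` implements a cost-utility comparison of
three strategies for a cohort of 1000 men aged 70 at entry:

* **SC** — whole-gland salvage cryotherapy, then watchful waiting until
  biochemical recurrence triggers first-line ADT;
* **ADT immediate** — everyone starts first-line ADT at entry;
* **ADT 20% deferred** — 80% start ADT immediately, 20% defer ("do
  nothing") and start at a constant monthly rate. This mixed strategy
  reflects usual practice and is the primary comparator.

## Model structure

The Markov model has four states — *pre-ADT* (disease-free after SC, or
deferred), *BDFS with ADT* (biochemical disease-free on first-line ADT),
*Progression* (second-line ADT, 40% with confirmed metastases at any one
time) and *Death* — with forward-only transitions. It runs in monthly
cycles over a 36-year horizon (432 cycles), by which time the cohort has
died. Costs and QALYs are discounted at 3.5% per year; life-years are
reported undiscounted. State occupancy propagates as a cohort trace
(`run_cohort()`); an individual-level microsimulation with identical rules
(`microsim_oracle()`) is kept purely as a validation oracle and agrees with
the trace to within binomial Monte-Carlo error (the test suite checks a
maximum occupancy deviation below 0.005 at 200,000 individuals).

Within a cycle, death is applied first and the clinical transition is
scaled to survivors. The model is silent on intra-cycle ordering in its
sources; this choice is explicit in `transition_matrix()` and documented
here. No half-cycle correction is applied in the base case; a
`half_cycle_correction` flag averages start- and end-of-cycle occupancy
instead.

### Recurrence after cryotherapy: the spline model

The time-dependent SC-to-ADT transition comes from a flexible parametric
(Royston–Parmar) survival model on the log-cumulative-hazard scale with one
internal knot:

$$\log H(t) = \gamma_0 + \gamma_1 \log t + \gamma_2\, s_1(\log t),$$

where $s_1$ is the restricted cubic basis, linear beyond the boundary
knots. The monthly transition probability for cycle $c$ is
$1 - \exp(-\max(0, H(c{+}1) - H(c)))$, which telescopes so that the
cumulative recurrence through cycle $n$ equals $1 - S(n)$ whenever the
hazard increments are nonnegative.

Base-case coefficients are $(-4.58, 1.01, 0.303)$ with standard errors
$(0.408, 0.096, 0.068)$, drawn as independent normals in the probabilistic
analysis (no covariance is available — a documented limitation). The knot
locations behind those published coefficients are not recoverable; the
packaged defaults place them at $\log 1$, $\log 24$ and $\log 120$ months.
Two consequences are worth stating plainly:

* Under these knots the fitted log-cumulative-hazard *declines* beyond
  roughly six months. The engine floors negative hazard increments at
  zero, so recurrence effectively stops and lifetime recurrence after SC
  is only a few percent. Headline outputs are therefore approximate
  reproductions: dominance, orderings and the cost-neutral window are
  preserved, but absolute SC-arm costs sit below the published ones.
* For simulation (`simulate_km_dfs()`) the same convention is applied as a
  monotone envelope (running maximum of $H$), keeping simulated data
  consistent with what the engine does.

`fit_spline_km()` fits the same model to right-censored data by maximum
likelihood through `flexsurv::flexsurvspline(scale = "hazard")`, with
boundary knots at the extremes of uncensored log event times and the
internal knot at a configurable quantile (default median). The
simulate-then-fit loop recovers generating coefficients within three
standard errors at $n = 2000$, the module's core correctness property.

### Relative risk of progression after SC

Patients who reach ADT after failed cryotherapy carry a relative risk
(base case 1.5, log-normal with natural-scale SD 1.38) of progressing
compared with primary ADT patients. The risk is applied on the hazard
scale, $p' = 1 - (1-p)^{\mathrm{rr}}$, which keeps $p'$ a valid probability
for the large draws the heavy-tailed log-normal produces; naive
multiplication would not. The log-normal is parameterised so its
*natural-scale* mean and SD equal the published point estimate and SE;
the source is ambiguous about the scale, and the `lognormal_from_mean_se()`
helper documents the conversion should a log-scale reading be preferred.

### Mortality

Background all-cause mortality applies in every alive state, converted
from annual probabilities by constant hazard within the year,
$q_m = 1 - (1-q_x)^{1/12}$. Prostate-cancer mortality applies as an
additional hazard in the Progression state only, combined as independent
competing risks within the cycle. The sources do not assign mortality
schedules to states; this assignment is configurable (the
`subtract_pc_from_background` flag additionally removes the
prostate-cancer hazard from the all-cause table to avoid double counting,
off by default).

Both schedules are synthetic, generated by `generate_life_table()` (a
Gompertz–Makeham law, $q_x = 1 - e^{-(c + a e^{bx})}$) and
`generate_pc_mortality()` (an exponentially age-increasing rate). Two
calibrations, chosen once and frozen:

* the life table ($a = 2.1\times10^{-5}$, $b = 0.102$, $c = 5\times10^{-4}$)
  gives a male period life expectancy at 70 of 13.2 years, the
  UK-2010-like magnitude the model assumes, with realistic age-specific
  probabilities (about 0.027 at 70, 0.071 at 80);
* the prostate-cancer schedule ($4\times10^{-4}$ per year at age 70,
  log-slope 0.07 per year) is calibrated against the decision problem's
  reported near-equality of life-years across arms — the only available
  anchor for this schedule, since the magnitude of prostate-cancer death
  among progressing patients is otherwise confounded with the unknown
  schedule the original analysis used. Under the defaults the base case
  shows between-arm life-year differences of about 0.04–0.05 years.

Neither table attempts to replicate actual ONS values row by row; the
packaged CSVs are labelled `synthetic_` accordingly.

## Costs, utilities and accumulation

All costs are GBP. The cost schedule (`state_cost_schedule()`) rolls unit
costs and resource-use quantities up into:

* a one-off SC procedure cost (£8509.38 at point estimates: ultrasound,
  2.5 h surgeon, 2 h theatre, consumables, needle kit, two overnight
  stays, 40 min catheter care, plus a fixed £33.75 peri-operative
  medication bundle). Resource-use quantities are gamma-distributed in the
  probabilistic analysis; unit prices are fixed. The catheter and nurse
  delivery times are carried as exact fractions (2/3 h and 1/3 h) so the
  published bold totals reproduce to within a penny;
* an expected acute adverse-event cost
  ($\sum_e p_e \cdot c_e \approx £1247$) over seven cryotherapy
  complications (fistula, incontinence, retention, lower urinary tract
  symptoms, perineal pain, haematuria, urethral stricture), charged
  uniformly over a 3-cycle window after the procedure (all events
  manifest within three months); an `ae_costs_at_cycle0` flag front-loads
  them instead, leaving the undiscounted total identical;
* first-line ADT at £83.22 per cycle (goserelin, expected hot-flush
  treatment at 10% uptake, nurse delivery), with the first cycle at
  £88.76 including the bicalutamide lead-in. The premium is charged on
  the *flow* entering the ADT state, which the cohort trace records;
* a Progression-state cost of £1229.27 per cycle at point estimates: the
  40/60 mixture of abiraterone (£2930) and the leuprorelin-based
  non-metastatic regimen (£95.44).

Utilities: 0.774 in both disease-free states (the sources do not
distinguish pre-ADT from ADT-maintained disease-free quality of life;
sharing the value is the package's default and configurable), and a 40/60
metastatic/non-metastatic mixture (0.42/0.68, i.e. 0.576 at point
estimates) in Progression. Of the acute adverse events only fistula
carries a published utility decrement (0.15); it is applied to the
expected fistula fraction during the adverse-event window. The other six
events are cost-only — the sources list no decrements for them.

The cost-neutral point (`cost_neutral_time()`) is the first crossing of
the cumulative *discounted* mean-cost-per-patient trajectories, linearly
interpolated within the cycle; discounted cumulative costs are what the
reported totals integrate, so the crossing is consistent with them (an
undiscounted variant is a one-line change via a zero discount rate). Under
the packaged defaults the SC-versus-deferred-ADT crossing falls at 3.16
years, inside the 3–4 year window the published analysis brackets.

## Probabilistic sensitivity analysis

`run_psa()` draws every uncertain parameter from its family — beta for
probabilities and utilities, gamma for costs and resource use, normal for
spline coefficients, log-normal for the relative risk — with shapes
derived from the published mean and SE by the method of moments. Each
parameter draws on an independent sub-stream seeded from the base seed and
the parameter's name, so results are reproducible bit-for-bit and adding a
parameter never perturbs the others' draws. One draw is shared across
strategy arms per iteration (common random numbers), sharpening the
incremental contrasts. The CEAC reports, for each willingness-to-pay
threshold, the probability that a strategy maximises net monetary benefit
$\lambda \cdot \mathrm{QALY} - \mathrm{cost}$; exact ties split
probability equally (a measure-zero event under continuous draws, handled
for completeness). The default threshold grid spans £0–£50,000 in £500
steps, covering the £20,000–£30,000 decision band.

## Scenario analyses

Five scenario transformations of the base case (`apply_scenario()`), all
pure functions of the parameter set:

1. **No abiraterone** — metastatic progression priced at the
   non-metastatic regimen (the sources quote "£97 per month" in prose but
   their own cost table rolls up £95.44; the table is internally
   consistent and is followed);
2. **Relative risk 2** for progression after SC;
3. **Alternative recurrence data** — the published alternative source does
   not print its survival parameters, so the scenario is a pluggable hook:
   any recurrence model accepted by `monthly_transition_prob()` can be
   passed to `sc_strategy()`. `example_alt_recurrence_model()` documents a
   Weibull (shape 1.2, median disease-free survival 60 months), a steeper
   profile of the magnitude long-term salvage-cryotherapy series report;
4. **Mean age 60**; 5. **Mean age 80** — the 432-cycle horizon is kept in
   both, matching how the original analysis kept a single horizon.

## Numerical choices

* Event-time inversion: bisection on a bracketed 512-point log-spaced
  grid, tolerance $10^{-8}$ months.
* Negative sampled hazard increments floored at 0; realised probabilities
  and utilities clamped to $[0,1]$ (beta draws already respect this);
  realised costs floored at 0.
* Transition-matrix rows are asserted to sum to 1 within $10^{-12}$, and
  the cohort trace conserves probability to the same drift bound over all
  432 cycles.
* Degenerate inputs: any distribution with a zero SE draws its point
  estimate; a beta specification requires $se^2 < m(1-m)$ and fails
  construction otherwise, naming the offending parameter.
* `simulate_km_dfs()` censoring is independent of the event process: with
  probability `censoring_rate` a subject draws a uniform withdrawal time
  on $(0, \mathrm{max\_follow\_up})$, otherwise administrative censoring
  applies at follow-up end. Independence keeps the Kaplan–Meier estimate
  consistent, which the test suite relies on.

## What the synthetic data do and do not show

The generators emulate the *structure* of the external inputs: a
Gompertz-shaped male life table, an age-increasing cancer mortality
schedule, and proportional-hazards spline recurrence data. Passing tests
demonstrate that the machinery — distribution sampling, cohort algebra,
discounting, incremental and probabilistic logic — is correct, and that
the qualitative economics (SC dominance, the cost-neutral window, the
scenario orderings) are robust under realistic magnitudes. They do not
certify the original absolute figures: those depend on the actual 2010 UK
tables and the unpublished spline knots. Quantities that survive this
uncertainty (the cost roll-ups, which are pure arithmetic on published
unit costs) reproduce to the penny.

## Problem sizes

The shipped test suite and acceptance script use 1,000 PSA iterations
(the original analysis ran 10,000 — the probability statements here are
already saturated at 1,000), a 200,000-individual microsimulation for the
oracle comparison, 50,000 draws for distribution-recovery checks, and
$n = 2000$ simulated subjects for spline-fit recovery. All sizes are
arguments, not constants.

## Known limitations

* Spline coefficient draws ignore the (unpublished) covariance between
  coefficients.
* The packaged knots are a convention, not a reconstruction; absolute
  SC-arm recurrence is understated under them (see above).
* No individual-level heterogeneity (nadir-PSA strata, potency strata):
  mentioned in the source material but never parameterised.
* No value-of-information analysis, no net-benefit regression, and no
  currency conversion — GBP throughout.
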