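---
title: "Methods: Markov cohort cost-effectiveness models for probiotic prophylaxis of pouchitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov cohort cost-effectiveness models for probiotic prophylaxis of pouchitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pouchcea)
```

## Scope and model structure

Pouchitis is the most common inflammatory complication after restorative
proctocolectomy with ileal pouch–anal anastomosis (IPAA) for ulcerative
colitis. `pouchcea` implements two discrete-time Markov cohort models that
compare daily prophylaxis with an 8-strain probiotic against no prophylaxis
from a third-party payer perspective:

* a **primary prevention** model for pouchitis-naive patients, with 2-week
  cycles chosen to match the length of an acute antibiotic course, and
* a **secondary prevention** model for patients with relapsing pouchitis,
  with 4-week cycles matching the longer courses used for recurrent disease.

Both models share a treatment ladder — ciprofloxacin, then metronidazole,
then ciprofloxacin + tinidazole — in which responders enter a line-specific
remission, later episodes are retreated with the previously effective
antibiotic, and failure of that antibiotic escalates one line. The
escalation-on-failure reading matters: without it, almost no one can reach
dual antibiotics (at base case only about 4% of two-year episode sequences
fail both first-line drugs directly), whereas with it the model reproduces
the observed reach of combination therapy in both arms. Treatment courses
are tunnel states (one cycle per 2- or 4-week course; the 4-week dual course
spans two cycles in the primary model), so a cohort member can neither start
a new episode mid-course nor stay in treatment longer than the course lasts.
Recurrence risk runs only in remission states.

In the secondary model, failure of dual antibiotics defines chronic
antibiotic-refractory pouchitis (CARP): a one-time evaluation cost, probiotic
discontinuation, vedolizumab with a primary response assessed at the end of a
two-cycle induction and an annual loss-of-response hazard among responders,
and infliximab as an absorbing terminal therapy with an assumed certain
response. We keep charging infliximab dosing through the horizon: an assumed
response ends disease activity, not drug cost. The primary model terminates
the ladder at dual antibiotics with an assumed certain response; the
`extended_biologics` variant relaxes that to the evidence-based 0.69 response
and continues to the same biologic pathway, which is how we verified the
truncation is innocuous (the headline classification does not change).

## Parameters

Every numeric input lives in a typed registry (`param_registry()`) carrying a
base-case value, a triangular Monte Carlo range, a role (probability, cost,
utility, structural) and an explicit time basis; names carry their unit
(`_annual`, `_2wk`, `_4wk`, `_dose`) because the models mix annual
probabilities with per-course and per-dose costs. Clinical names that appear
in both models with different Monte Carlo ranges (for instance the
ciprofloxacin response) are stored once per model scope and resolved by
`load_defaults()`. Two structural probabilities are deliberately degenerate —
the dual-antibiotic response in the base primary model and the infliximab
response — and are therefore never varied in the PSA.

Key defaults: annual first-episode probability 0.10 (probiotic) vs 0.40
(none); annual relapse probability 0.14 vs 0.39; annual recurrence after an
index episode 0.39; antibiotic responses 0.77 / 0.70 / 0.69; vedolizumab
response 0.52 with 0.40 annual loss; utilities 0.91 (no pouchitis) and 0.46
(active pouchitis) per year; probiotic $87.2 per 2 weeks or $174 per 4 weeks;
workup $612.6; CARP evaluation $128.4; vedolizumab $6,803 and infliximab $987
per 300 mg dose. Infliximab is dosed at 5 mg/kg for the 70 kg base-case
adult, pro-rated linearly to $1,151.50 per dose; vial rounding would be a
straightforward alternative but the linear pro-rating is the default.

Biologic label schedules (doses at weeks 0, 2 and 6, then every 8 weeks)
cannot sit exactly on a 4-week grid. We encode one dose on the entry cycle
and two on the next (weeks 2 and 6 fall in the second cycle), then one dose
every second cycle; on the 2-week grid of the extended primary variant the
induction doses land exactly on cycles 0, 1 and 3 with maintenance every
fourth cycle. Either compression conserves the three induction doses.

## Reward conventions

Cycle lengths are defined as 1/26 and 1/13 of a year, so a 2-year horizon is
exactly 52 or 26 cycles and the constant-hazard conversion
`1 - (1 - p_annual)^(cycle_years)` compounds exactly over integer years
(two-year cumulative incidence at annual risk 0.40 is exactly 64%).
State-membership rewards (annual utility × cycle length; per-cycle probiotic
and biologic costs) accrue for the whole cycle at the cycle-start discount
factor, with no half-cycle correction by default; `run_cohort(half_cycle =
TRUE)` switches membership rewards to the start/end occupancy average for
sensitivity to that convention. One-time costs (workup, antibiotic courses,
CARP evaluation) are charged on the transition into the treating state,
discounted at the destination cycle. Discounting uses `(1 + r)^(-t)` at an
annual rate of 3%.

These conventions are stated prominently because cumulative accruals are
sensitive to them: choices of half-cycle handling, reward timing and horizon
can move absolute 2-year costs and QALYs by tens of percent while leaving
ratio quantities (ICERs) and decision thresholds comparatively stable. The
package fixes one explicit, internally consistent convention and exposes the
switches rather than tuning them toward any external figure.

## Analyses

**Base case.** `run_cohort()` propagates the cohort and accrues rewards;
`cea_compare()` reports per-strategy cost and QALYs, ΔC, ΔE, the ICER, net
monetary benefit `NMB = λΔE − ΔC`, and a dominance/WTP classification at
λ = $100,000/QALY. Classification and NMB agree by construction (ties at
zero resolve to cost-effective). One- and five-year horizons are plain
re-runs with different cycle counts.

**One-way sensitivity analysis.** `owsa_sweep()` evaluates the full pipeline
on an equally spaced grid (199 points by default, matching whole-percent /
whole-dollar reporting) and refines every classification change by local
bisection to 1e-4 of the sweep range; `find_threshold()` bisects the
acceptability indicator directly and returns the zero-NMB crossing. Sweeps
may exceed the Monte Carlo ranges but never role bounds. For parameters that
enter cost linearly (drug prices) NMB is affine in the parameter, and the
test suite checks bisection against the analytic root.

**Probabilistic sensitivity analysis.** `run_psa()` interprets the Monte
Carlo analysis as second-order uncertainty: each draw samples every
parameter with a range independently from triangular(min, mode = base, max)
and evaluates the deterministic cohort pipeline. Draws are mutually
independent because no correlation structure is specified for these inputs.
One seeded generator samples parameters in registry order — the order is
part of the reproducibility contract — and utility pairs violating
no-pouchitis ≥ active-pouchitis are jointly resampled, so no draw carries
sign-inverted utilities. `ceac()` reports, per willingness-to-pay value, the
fraction of draws with positive NMB.

**Microsimulation oracle.** `simulate_patient()` /
`estimate_by_simulation()` replay the same transition rules and the same
reward code path patient by patient. All of a patient's transition uniforms
are pre-drawn as one patients × cycles matrix from the master seed, so a
patient's trajectory does not depend on evaluation order. The oracle exists
to validate the cohort engine (the suite requires every state-by-cycle
occupancy cell to sit within 4 binomial standard errors at 50,000 patients,
with cost and QALY means within 4 standard errors); it is not an alternative
analysis path. A second, deliberately independent accrual implementation
lives only in the test suite for double-entry checking of the reward rules.

## Numerical choices and degenerate inputs

Transition matrices are validated every cycle (row sums within 1e-12);
occupancy conservation is asserted to 1e-10. Annual probabilities of exactly
1 convert to per-cycle probability 1. Degenerate triangular ranges (min =
mode = max) are point masses, which is also how structural parameters are
excluded from the PSA; collapsing every range onto the base value makes each
draw reproduce the base case exactly, a property the tests exercise.
Probabilities may be swept to their role bounds (0 and 1) inclusive.
Bisection assumes a single acceptability crossing inside the bracket and
errors when the endpoints agree.

## What the synthetic data do and do not show

The generator (`generate_test_parameters()`, the PSA sampler, and the
microsimulation) emulates exactly the stated study conditions: tabulated
base-case values, triangular parameter uncertainty with the tabulated
ranges, and trajectories consistent with the cohort transition rules. It
does not emulate features of real cohorts that the models themselves omit —
no background mortality, no pouch failure or dysplasia, no seasonal or
age-dependent risks, no correlation between parameters, and no
patient-level heterogeneity beyond state membership. Passing tests
demonstrate internal consistency of engine, oracle and analyses under these
conditions; they are not evidence about real-world effectiveness, where in
particular the probiotic's preventive efficacy has been reported lower than
in trials.

## Known limitations

* Absolute cumulative costs and QALYs depend materially on the accrual
  conventions above; ICERs, classifications and thresholds are the stable
  outputs and are what the acceptance checks emphasise.
* The published figures this family of models is usually compared against
  contain internally inconsistent absolute accruals; the package documents
  its own convention rather than reverse-engineering any particular figure,
  and the test suite states each reproduction tolerance explicitly, leaving
  out-of-reach comparisons visibly failing rather than silently loosened.
* The one-way analysis is strictly one-way; no two-way interactions or
  tornado ranking are provided.
* The PSA draws parameters independently; correlated uncertainty (for
  example between the two arms' event probabilities) is not modelled.
```{r example}
ps <- load_defaults("primary")
arms <- build_primary(ps)
cea_compare(run_cohort(arms$probiotic, ps, 2),
            run_cohort(arms$no_prophylaxis, ps, 2))
```
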