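---
title: "A three-state model of migraine: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state model of migraine: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(migstates)
```

## The model

Cross-sectional migraine epidemiology distinguishes only two states: active
migraine (symptoms within the last year) and its complement. That complement,
however, pools two very different groups — people who never had migraine and
people whose migraine has gone into remission. `migstates` estimates the three
states separately:

* **S0, never migraine** — no migraine symptoms at any point in life;
* **Ca, active migraine** — symptomatic activity within the last year;
* **Ci, inactive migraine** — previously active, no activity in the last year.

Transitions are governed by three age-dependent hazards: first incidence
`i0(a)` (S0 to Ca), remission `r(a)` (Ca to Ci), and reactivation `f(a)`
(Ci to Ca). The cohort is closed: no differential mortality between states is
assumed, so the three occupancies always sum to the cohort size. Individuals
can leave the inactive pool only by becoming active again (or dying, which
affects all states equally and therefore cancels from the proportions).

None of the three hazards is directly observable from routine data. The
package recovers them from two published sources:

1. **Age-by-year prevalence and incidence of active migraine** (the layout of
   a GBD Results Tool extract). In the two-state view the prevalence `p` of
   the active state obeys the illness-death balance equation
   `dp/da + dp/dt = i (1 - p) - r p`, so once smooth surfaces `p(a, t)` and
   `i(a, t)` with analytic partial derivatives are available, the remission
   hazard is identified as `r = (i (1 - p) - dp/da - dp/dt) / p`.
2. **Lifetime prevalence by age group and sex** (the layout of a
   population-based survey with groups 25–34 … 55–64). The lifetime
   prevalence `q0` is modelled logit-linearly in age with a sex main effect
   and an age-by-sex interaction. Because the ever-had-migraine pool can only
   be entered, the first-incidence hazard among the never pool is the
   susceptible-pool relation `i0 = q0' / (1 - q0)`, which for the logit-linear
   form reduces to `i0 = (b1 + b3 s) q0`. Never-migraine prevalence is
   `p0 = 1 - q0`.

The reactivation hazard is not identified by either source alone. It is pinned
by a balance identity with the pooled incidence reported for the whole
no-active group: requiring the extended model's inflow into the active state,
`i0 S0 + f Ci`, to equal `i_gbd (S0 + Ci)` gives
`f = (i_gbd (S0 + Ci) - i0 S0) / Ci`, evaluated at the current state occupancy
during the simulation.

The three pieces are combined in a deterministic discrete-time cohort: an
explicit Euler recursion with step `h` updates the three occupancies,
conserving the total exactly; prevalence curves are occupancy proportions at
each step.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `degree_age` (surface) | 12 | – | see below |
| `year_effect`, `interaction` | on | – | allows secular trend and its age modulation |
| `weighted` (surface) | off | – | inverse-UI-variance weights are available but not assumed |
| `n_resamples` (remission) | 1000 | – | percentile bands stabilise well before this |
| `n_samples` (lifetime) | 5000 | – | resampled regressions; median pooling |
| cohort `N` | 100{,}000 | persons | presentation scale; dynamics are proportions |
| `start_age`, `start_year` | 30, 1990 | years | cohort enters at age 30 in 1990 |
| `follow_up`, `h` | 30, 0.01 | years | 3001 recursion steps to age 60 |
| `eps` (reactivation guard) | 1e-6 | of pool | empty-pool fallback `f = i_gbd` |
| `f_max` (reactivation cap) | 0.5 | per py | truncates the ill-conditioned small-pool identity |
| `i0` support | 15–80 | years | lifetime model anchored at ages 29.5–59.5 |

**Why a degree-12 age polynomial?** The surfaces are fitted by ordinary least
squares on a transformed scale (logit for prevalence, log for incidence) with
a polynomial in centred, rescaled age, a linear year term and an age-by-year
interaction. The remission stage consumes the *derivative* of the fitted
surface, and dividing by `p` further amplifies errors where prevalence is
small. A low-degree polynomial leaves smooth-fit bias that is larger than the
resampling bands it is compared against; with the 17+ age-group midpoints of
a full extract, degree 12 drives that bias well below the band width (on
noiseless synthetic worlds, inversion error is below ~4% at interior ages)
while remaining an ordinary, analytically differentiable linear fit. The
degree is configurable (`surface_spec()`), and is automatically capped at
(number of distinct midpoints − 1) for sparser inputs.

**Resampling scheme.** Uncertainty intervals are converted to sampling noise
by the normal rule `sd = (upper - lower) / (2 * 1.96)` applied per record;
prevalence draws are truncated to [0, 1] and incidence draws to nonnegative
values. Both surfaces are refitted per resample and the remission curve
recomputed; the point estimate is the age-wise median, the band the 2.5th and
97.5th percentiles. The same normal rule generates the lifetime-prevalence
resamples; draws outside (0, 1) are treated as missing because the logit is
undefined there (the lower truncation mirrors the treatment of negative
draws; the upper one is its symmetric counterpart).

**Admissibility and pooling.** A lifetime regression is admissible if the
implied lifetime prevalence increases with age for both sexes (`b1 > 0` and
`b1 + b3 > 0`); inadmissible sets are excluded and the survivors pooled by
coordinate-wise median. Sex is coded 0 = male, 1 = female; the coding only
permutes the interpretation of `b2`/`b3` and is recorded in run metadata.

## Numerical choices and degenerate inputs

* Negative remission rates from the inversion are **retained, flagged** in
  raw output (they diagnose surface misfit) and clamped to zero only where a
  proper hazard is required (the cohort simulation).
* The reactivation identity divides by the inactive-pool occupancy. Near an
  empty pool (`Ci < eps` of the no-active pool) the fallback `f = i_gbd` is
  used — the identity's exact limit when `i0 = i_gbd`; solutions above
  `f_max` are truncated and negative ones clamped, all flagged.
* Cohort initialization takes the active occupancy from the prevalence
  surface and the never occupancy from the lifetime baseline; if together
  they exceed the cohort, the inactive state is floored at zero, the never
  state rescaled, and the state flagged — never silently.
* The Euler step guard refuses `h * hazard >= 1`; at the default `h = 0.01`
  and epidemiologic hazard magnitudes the discretization error at the end of
  follow-up is well below 0.1% (halving `h` is part of the test suite).
* Transformed responses are clamped away from {0, 1} (logit) and 0 (log) by
  `eps = 1e-10` before fitting, so zero-valued records do not produce
  infinities.

## The synthetic ground truth

`ground_truth()` defines a world by its three hazards; `solve_truth()`
integrates it exactly (fixed-step fourth-order Runge–Kutta, step 0.0025
years, everyone disease-free at age 10) and derives the pooled incidence
`i_gbd = (i0 S0 + f Ci)/(S0 + Ci)` and lifetime prevalence `q0 = 1 - p0`.
`emit_gbd_tables()` and `emit_lifetime_table()` then write the two input
layouts with controlled noise, so every stage has a parameter-recovery
oracle.

The default hazards echo the magnitudes of migraine epidemiology, chosen once
at design time: female first-incidence rising from 0.33%/yr at 25 to 0.54%/yr
at 65 (male 0.08% to 0.13%), remission rising from about 1.5 to 6.5 per 100
person-years across adulthood, and a constant reactivation hazard of 1 per
100 person-years. This produces a female active-prevalence profile of
realistic size (peaking under 10%) and near-zero inactive prevalence at age
30, rising steadily thereafter.

What the generator deliberately does **not** emulate: secular trends (the
truth is time-invariant, so the fitted year terms are exercised but not
stressed), differential mortality, probable-vs-definite diagnostic grades,
and the estimation machinery behind real GBD uncertainty intervals (noise is
independent multiplicative normal per record). Passing recovery tests on
these worlds therefore validates the estimation chain under the model's own
assumptions; it cannot certify those assumptions against real data.

## Design choices where the design was open

* **One joint model across years** rather than per-year fits: a single
  surface with year terms borrows strength across 30 extraction years and
  yields the calendar-time partial analytically. Dropping that partial is a
  flag (`include_dt = FALSE`) for sensitivity.
* **Median pooling before evaluating `i0`** (pool coefficients, then build
  the curve) matches the admissibility-filter logic: the pooled set is
  guaranteed monotone, which pointwise pooling of curves would not be.
* **Deterministic compartment counts**, not individual-level random walks:
  the recursion conserves the total exactly and the quantities of interest
  are expectations; `N = 100,000` is retained for presentation only.
* **Fit over all extracted midpoints, report 17.5–72.5**: the full support
  stabilises the polynomial; the reporting window avoids the open-ended
  oldest group and the sparse youngest ones.

## Problem sizes used in validation

The packaged checks run a full synthetic pipeline at its defaults (30
extraction years, 17 age groups, 2 sexes), with reduced Monte-Carlo sizes
chosen as the smallest that leave the checked tolerances comfortably
non-binding: 200 remission resamples for band coverage, 300–1000 lifetime
resamples for coefficient recovery, and a 0.005-year integration step for
the ground truth.

## Known limitations

* The polynomial inversion is edge-biased: below ~age 20 (tiny prevalence,
  sharp logit knee) and above ~75 (open-ended age group) recovered remission
  rates can deviate substantially; interior ages are accurate. The reporting
  default stays inside 17.5–72.5.
* The lifetime stage extrapolates a logit-linear form fitted on ages
  29.5–59.5 to the cohort entry age of 30 and, through `i0`, to 60; curvature
  in true lifetime prevalence is absorbed into the pooled slope.
* A lifetime table from one population and era is combined with
  prevalence/incidence surfaces from another; the package assumes the
  lifetime curve is stable and transportable, and offers no check of that
  assumption.
* No differential mortality: if active or remitted migraine alters survival,
  all three prevalences are biased in older age groups.
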