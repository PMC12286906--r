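---
title: "A dependence-state Markov cohort model for independence-preserving interventions in dementia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dependence-state Markov cohort model for independence-preserving interventions in dementia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depcem)
```

## The model

`depcem` implements a cohort state-transition (Markov) model for
cost-utility analysis of hypothetical interventions that preserve
independence in activities of daily living (ADL) in people living with
dementia. Health states are defined by dependence rather than
cognition, using the Bristol Activities of Daily Living Scale (BADLS,
0–60, higher = more dependent): **low** (0–14), **moderate** (15–29),
**high** (30+), plus an absorbing **dead** state. Dependence is treated
as stepwise and irreversible — people move only down the chain

low → moderate → high → dead,

with a competing move to dead from every alive state and no skipping
within a single cycle. The cycle length is 3 months and the base-case
horizon 10 years (40 cycles), which approximates a lifetime horizon for
a cohort entering at age 80. The analysis takes the perspective of the
health and social care provider in England (GBP, cost-year 2019/20),
with an optional societal perspective that adds per-state informal-care
costs.

The cohort enters distributed 60/24/10/6% across low/moderate/high/dead
— the end-of-study distribution of the trial sample the model is built
around, including the 6% who died during that study. The dead entrants
accrue nothing and never incur the death-event cost; they simply dilute
the per-person averages, which are reported over the whole cohort.

Per-cycle inputs (the packaged base case, `base_case_parameters()`):

| parameter | value |
|---|---|
| progression low→moderate / moderate→high | 0.15 / 0.07 per cycle |
| death from low / moderate / high | 0.02 / 0.038 / 0.05 per cycle |
| care cost low / moderate / high | £1,738 / £3,239 / £8,510 per cycle |
| death-event (non-elective admission) | £3,519 one-off |
| utility low / moderate / high / dead | 0.788 / 0.750 / 0.714 / 0 |
| discount rate (costs and QALYs) | 3.5%/year beyond the first year |
| intervention cost | £570 per person |

Death probabilities are conversions of published interval survival by
dependence level under a constant-hazard assumption
(`death_prob_per_cycle()`); progression probabilities come from
interval-censored longitudinal BADLS data (`estimate_transitions()`,
below); utilities are per-state means of EQ-5D-5L-style index values
(`estimate_state_utilities()`).

## The intervention operator

The hypothetical intervention acts once, at model entry: a sample-level
effect $e$ moves a fraction $e$ of the moderate-state occupancy to low
and a fraction $e$ of the high-state occupancy to moderate, both
computed from the *pre-intervention* proportions:

$$ l' = l + e\,m,\qquad m' = m - e\,m + e\,h,\qquad h' = h - e\,h, \qquad d' = d. $$

Two design choices deserve justification.

*Relative, not absolute.* We read "a sample-level effect of $e$" as
scaling the donor state's occupancy rather than moving $e$ percentage
points of the whole sample. Threshold effects of 12.5% and 27.5% are
meaningful quantities in the scenario analyses, yet only 10% of the
sample has high dependence at entry — the absolute reading would be
infeasible there, while the relative reading is feasible for all
$e \in [0,1]$ and makes net costs and QALYs exactly linear in $e$, as
the published scenario grids exhibit. The absolute reading is still
available (`apply_intervention_effect(..., mode = "absolute")`) and
errors when a donor state runs out of occupancy.

*Simultaneous, not sequential.* Both moves are taken from the
pre-intervention proportions, so the moderate pool is not enlarged by
the high→moderate move before the moderate→low move is taken. This
makes the operator order-independent and additive over donor states:
the full effect decomposes exactly into the moderate-only ("sub-group")
component plus the high-only component, a property the test suite
asserts to 1e-9.

After entry, both cohorts use identical transition probabilities: the
effect is a one-off preservation of independence with no downstream
modification of progression — a deliberately conservative reading.

## Accounting conventions and their calibration

Cost and QALY accumulation is

$$ C = \sum_t w_t \Big[ \sum_{s\,\text{alive}} \pi_t(s)\, c_s + \delta_t\, c_\dagger \Big] + c_{\text{int}}, \qquad
   Q = \sum_t w_t \sum_{s\,\text{alive}} \pi_t(s)\, \max(0, u_s - \Delta(a_t))\, \ell, $$

with $\pi_t$ the trace occupancy, $\delta_t$ the proportion newly dead
in cycle $t$, $c_\dagger$ the death-event cost, $c_{\text{int}}$ the
undiscounted intervention cost at entry, $\Delta(a)$ the age decrement,
and $\ell$ the cycle length in years. Published tables under-determine
four conventions in this formula; rather than hard-coding folklore,
`calibrate_conventions()` searches all 24 combinations and selects the
one minimising the summed absolute error against two published
base-case anchors (the 10-year no-intervention per-person cost and the
net cost at the smallest published effect):

* **Discount weighting** $w_t$. Compound annual discounting
  ($1.035^{-y}$ by completed year $y$) undershoots the published
  10-year total by ~9%, far outside any rounding. The published totals
  for both horizons sit ~3.3% and ~1.9% below their undiscounted sums —
  consistent with a *single* division by 1.035 applied to everything
  accrued beyond the first model year, i.e. a literal one-step reading
  of "discounted at 3.5% beyond the first year". The engine implements
  `one_step` (selected), `annual`, and `cycle` methods.
* **Accrual points.** Valuing the entry row plus every
  end-of-transition row ($t = 0..40$, 41 points) reproduces both
  horizon blocks to within 1%; valuing 40 start-of-cycle points cannot
  reach the published 5-year cost at all (it exceeds the undiscounted
  40-point sum). The 41-point convention is selected
  (`include_final_row = TRUE`).
* **Half-cycle correction.** None; any half-weighting of the end
  points moves totals ~£2,000 away from the anchors.
* **Intervention-cost denominator.** Charged across the whole entry
  cohort, including the 6% entering dead (`"cohort"`); the alive-only
  alternative misses the net-cost anchor by ~£32.

The winning conventions are the package defaults, and the calibration
is re-run (not assumed) by the acceptance script and test suite.

### What still does not reproduce exactly

With the *printed, rounded* inputs above, the calibrated model matches
the published per-person and 5-year costs to 0.3–1%, all published net
QALYs to the printed fourth decimal, and the 2.5%-effect ICER to 0.2%.
It does not exactly match the published incremental-cost slope: care
savings per unit effect compute to −£6,110 here versus ≈ −£6,187
implied by the published nets. That ~1.2% gap is immaterial for totals
but is amplified in small-difference ratios: the 7.5% ICER computes to
£8,923 versus the published £8,509, and the 12.5% sub-group ICER to
£13,674 versus £12,523. The pattern (moderate-donor component too
small, high-donor component too large, in both costs and QALYs) is what
one expects if the original analysis used unrounded internal parameters
— e.g. an entry distribution from raw participant counts and death
probabilities carried at full precision from the survival source —
none of which are printed. We deliberately do not tune any input away
from its printed value to close the gap; the corresponding acceptance
checks are left failing and documented rather than loosened.

## Parameter-derivation stages

**BADLS categorisation** (`categorize_badls()`) partitions 0–60 at
14/15 and 29/30.

**Progression estimation** (`estimate_transitions()`) consumes a panel
of (subject, month, BADLS) with irregular assessment intervals. Each
consecutive within-subject pair is classified by start state; a move up
is an event (backward moves, which the irreversible model excludes, are
counted as non-events and reported so the decision is auditable;
skipped-level pairs count as an event for the start state's stratum and
are reported separately). Pairs are stratified by interval length
rounded to the nearest month; each stratum's empirical proportion
$p_\Delta$ is rescaled to the 3-month clock under constant hazard,
$p_3 = 1-(1-p_\Delta)^{3/\Delta}$, and strata are combined by
exposure weighting (pairs × interval). This estimator reproduces the
direct proportion when intervals are exactly 3 months and is validated
by parameter recovery against the package's own panel generator
(±0.02 at 2,000 subjects, fixed seed). A stratum in which every pair
transitions has unbounded hazard and is dropped with a warning.
Mortality is never estimated from the panel; it comes from
`death_prob_per_cycle()` applied to published survival.

**Utility estimation** (`estimate_state_utilities()`) is the per-state
arithmetic mean, erroring when any alive state has no records.

## Synthetic data

Because the underlying trial and panel data are not redistributable,
two generators emulate their statistical structure so that every
pipeline stage is testable end-to-end:

* `generate_trial_cohort()` — an end-of-study snapshot: states
  allocated to a target 60/24/10/6 distribution (largest-remainder
  exact allocation by default, mirroring how the model cohort was
  constructed proportionally to the trial sample; multinomial mode for
  sampling-noise studies), BADLS scores uniform within the state's
  band, and utilities from a truncated normal (index range −0.594 to 1)
  whose location is recentred so the *post-truncation* mean equals the
  state mean. The dispersion (SD 0.15) is a generator choice made once
  to exercise estimator averaging; it is not an estimate from any
  study. Default size 354.
* `generate_panel()` — 565 subjects by default, latent states evolving
  forward-only in 3-month steps under a true transition model (with
  death), visits at jittered intervals (6 ± 2 months by default,
  a stand-in: the source study's actual visit-interval distribution is
  not described) up to 55 months with per-visit dropout (3%). Baseline
  states are drawn 50/35/15 over the alive states so both progression
  strata accumulate pairs; this mirrors a mild-to-moderate community
  cohort.

What passing these tests shows is that the estimators recover known
generating parameters from data with the right *shape* (irregular
intervals, dropout, banded scores). What they cannot show is robustness
to features the generators do not emulate: two-arm structure,
informative dropout, measurement error that crosses band boundaries,
or real visit-interval distributions.

## Numerical choices

* Occupancy conservation and matrix-row sums are enforced at 1e-12;
  config round-trips are exact at YAML precision 15.
* `threshold_effect_search()` uses grid search when a grid is given
  (smallest qualifying multiple), else bisection on the
  cost-effectiveness classification to 1e-4 on $e$ (the default),
  after asserting ICER monotonicity; a cost-saving, QALY-losing
  south-west quadrant is handled by the sign-aware classifier.
* Exact allocation ties break by largest fractional remainder, then
  first-listed state.
* Degenerate inputs error early and by name: zero survival (infinite
  hazard), empty effect grids, panels without eligible pairs, societal
  runs without informal costs, non-integer cycle counts.
* Age decrements enter as $\max(0, u_s - \Delta)$; a state-independent
  decrement provably cancels from incremental costs and perturbs
  incremental QALYs only through survival differences — asserted
  numerically — which is why incremental results are reported with the
  zero-decrement default while absolute QALYs would need the (not
  redistributed) age-decrement table supplied via
  `decrement_schedule`.

Problem sizes used by the test and acceptance suites — 100,000
individuals for the microsimulation oracle (agreement within 3
standard errors), 2,000-subject panels for transition recovery, a
40,000-subject widened-distribution cohort for utility recovery
(Monte-Carlo s.e. ≈ 0.002 in the smallest stratum against the ±0.005
criterion), and 1,000,000 draws for allocation convergence — were
chosen so that each stochastic check has comfortable power at a fixed
seed.

## Known limitations

* Deterministic only: no probabilistic sensitivity analysis, CEACs or
  EVPI; parameters carry no uncertainty distributions.
* Transition probabilities are time-homogeneous; there are no tunnel
  states and no age-dependent mortality beyond the per-state
  probabilities.
* The intervention effect exists only at entry; durable effects would
  make the intervention look better than modelled here.
* Care-partner quality-of-life effects are not modelled; the societal
  perspective captures informal-care *costs* only, and only when the
  user supplies per-state values.
* No currency conversion or inflation adjustment; England-specific
  value sets and thresholds.

## A worked run

```{r}
params <- base_case_parameters()
suite <- run_scenario_suite(params, effects = c(0.025, 0.05, 0.075, 0.10))
render_cea_table(suite)[, c("Sample-level effect", "Cost per person",
                            "Net cost", "Net QALYs", "ICER")]
threshold_effect_search(params, intervention_cost = 570,
                        grid = c(0.025, 0.05, 0.075, 0.10))$effect
```
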