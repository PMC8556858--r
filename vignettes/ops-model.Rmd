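---
title: "A discrete-time stochastic model of opioid use with an overdose prevention site"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete-time stochastic model of opioid use with an overdose prevention site}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`opsim` simulates a population of people who use opioids moving, in
30-minute steps over one year, between six states: not currently using
(State 1), using outside an overdose prevention site (State 2), using
inside the OPS (State 3), treatment/recovery (State 4), nonfatal overdose
(State 5) and fatal overdose (State 6, absorbing). The process is
Markov-type: transition probabilities depend only on the current state,
with one deliberate exception — entry into the OPS state is limited by the
site's finite capacity, so that transition depends on how many other users
are attempting entry at the same step.

Each step, an active user initiates use with probability
`uses_per_day / steps_per_day` (1/12 at the baseline of four uses per day
and 48 half-hour steps), so a use occasion occupies exactly one step. A
user who initiates use while the site is open attempts the OPS with a
probability that decays with distance (next section); attempted entries
beyond the remaining capacity are redirected — a uniformly random subset
of attempters is admitted, the rest use outside in the same step (they do
not defer the use occasion, which would distort the four-uses-per-day
budget). Outside use resolves to a fatal overdose with the per-use hazard
`p_f`, a nonfatal overdose with `p_nf`, otherwise back to State 1. Use in
the OPS overdoses with probability `ops_od_proportion * (p_f + p_nf)` and
is *always* revived: no fatal overdose can originate in the OPS, matching
what operating sites report. Each in-OPS overdose is additionally tagged
"counterfactually fatal" with probability `p_f / (p_f + p_nf)` — the
probability it would have been fatal outside — which gives an in-run,
variance-reduced estimate of fatalities averted. Treatment entry is a
per-step hazard from State 1 (users spend well over 90% of steps there, so
the annual aggregate matches the nominal rate), relapse is a per-step
hazard from State 4, and new users arrive as Poisson events at
`new_entrants_per_day / steps_per_day`, allocated to rings by population
proportion.

## Rate conversions

All annual probabilities are converted by complement compounding:
`q = 1 - (1 - p_annual)^(1 / n)` over `n = 17,520` half-hour steps, and
per-use overdose hazards use `n = 1,460` annual use events. The published
material does not state the conversion formula; compounding is the
convention consistent with the published equilibrium treatment population:
with 55,000 active users, 15%/yr entry and 50%/yr relapse the balance
point `55,000 * q_in / q_out` is 12,896 ("nearly 13,000"), whereas simple
division would give 16,500. Overdose hazards are attached to *use events*
rather than to elapsed time because overdoses can only arise from using
states; this choice also reproduces the direct-effect magnitude of about
six averted fatalities per 30 stations.

Two analytic oracles close the loop on these conventions:
`equilibrium_treatment_count()` (above) and
`expected_annual_events_no_ops()`, the deterministic mean-field recursion
of the step dynamics. Because every transition is a binomial thinning,
expectations propagate exactly, so the mean-field values (1,044 fatal,
3,934 nonfatal at baseline) are the exact expectations the stochastic
replicate means must approach.

## Geography

Distance from the site is discretised into thirteen contiguous rings: the
closed inner ring `[0, 0.25]` miles, half-open rings `(a, b]` out to six
miles, and an open-ended outer ring. Each ring carries a visit scale taken
from a published table derived from New York City safe-injection-facility
survey data; the per-use probability of attempting the OPS is
`0.67 * scale`, from 0.67 in the inner ring to 0.0018 beyond six miles.
The source table skips the `(3, 3.5]` interval; we treat that as a
typographical gap and restore the ring with the geometric interpolation
`sqrt(0.09 * 0.051) = 0.0677` of its neighbours, which is what an
exponential decay in distance implies. `fit_distance_decay()` fits that
exponential (ordinary least squares of log scale on distance through the
origin, using ring midpoints) to predict scales at unmeasured distances;
whether the original fit used midpoints or edges is not stated, and at
ring width 0.25-0.5 miles the difference is well below the table's own
rounding.

## Synthetic overdose records

The record-level overdose data behind the original analysis are available
only by request from the Philadelphia Department of Public Health, so the
package generates synthetic records that reproduce every printed summary
the downstream analyses actually consume: 1,033 fatal and 3,788 nonfatal
events per year; cumulative spatial shares of 30% of users within one
mile of the candidate site and 38% within 1.5 miles; and the published
demographic marginals (for nonfatal events no race/ethnicity breakdown
was published, so those fields default to "unknown").

Distances are drawn from a two-component mixture: a near-site exponential
(weight `w`, rate `lambda`) plus a uniform far-field tail on `(1.5, 10]`
miles. The two printed cumulative shares give two equations in the two
free parameters, solved numerically so the analytic CDF passes through
both targets to better than 1e-9. At the default targets this yields
`lambda = 0.81` per mile and `w = 0.54`. The far-field shape beyond 1.5
miles is *not* constrained by any printed number; the uniform tail is a
deliberate, minimal assumption, and per-ring proportions beyond the two
calibrated shares are not claimed to match the unpublished distribution.
The default ring profile bins 60,000 synthetic distances (binomial error
per ring below 0.002). Demographics are sampled independently of distance
and fatality by default, because joint distributions were not published;
an optional linear-in-distance gradient can tilt the White share upward
near the site for demonstrations of the equity analysis (near-site fatal
overdoses over 80% White).

A pleasant consequence of this calibration: the attendance-weighted
population shares put roughly 74% of expected OPS admissions within one
mile and 86% within 1.5 miles, matching the published attribution of
revivals (74%/86%) even though those figures were never used as targets.

## The engine and its oracle

Counts per (state x ring) are advanced with vectorized binomial,
multivariate-hypergeometric (capacity allocation) and Poisson draws, for
a whole batch of replicates simultaneously. Aggregated sampling is
exactly equivalent in distribution to independent per-agent chains — a
sum of i.i.d. Bernoulli decisions is binomial, and a uniformly random
admitted subset across rings is hypergeometric — and the package carries
a per-agent microsimulation, `simulate_year_microsim()`, implementing the
same rules agent by agent; the test suite verifies the two engines agree
in distribution on 500-agent cohorts. Conservation (alive + cumulative
fatal = initial + cumulative entrants) is asserted at every step of every
replicate.

Within a step the order is fixed: use initiation, OPS admission, use
resolution, overdose resolution, treatment entry/relapse (both drawn from
stage-start compartment sizes), then new entrants. All per-step hazards
are of order 1e-5 to 1e-1, so ordering effects are far below Monte-Carlo
error. The OPS is open the first 40 steps of each model day; under
baseline demand (roughly 900 attempted entries per open step against at
most 300 stations) the site is saturated whenever open, so which 20 hours
are open does not affect annual totals. A use occupies exactly one step
and the nonfatal-overdose state resolves within the step it is entered;
the published material gives no durations, and one step is the minimal
choice consistent with the saturation arithmetic.

Randomness: each batch consumes one R RNG stream seeded by the master
seed, so a result is reproducible from (seed, replicate count) alone;
scenario drivers derive one child seed per arm. Same seed and settings
give byte-identical results.

## Common-random-numbers pairing

Scenario differences (an OPS arm minus the no-OPS baseline; a raised
treatment rate minus the 15% baseline) are small — tens of events per
year — against a per-replicate standard deviation of ~63 nonfatal events,
so independent arms need thousands of replicates to resolve them. The
package therefore offers exact common-random-numbers couplings alongside
independent differencing (`pairing = "independent"`), which remains the
construction behind the published sweep figures. Pairing never changes an
expected difference, only its variance, and the test suite asserts that
paired and independent estimates agree within combined Monte-Carlo error.

*Capacity pairing (revived tagging).* In a capacity run, a user whose
in-OPS overdose is flagged counterfactually fatal is moved to a tagged
copy of the active/treatment compartments. Tagged users follow identical
transition rules — the run's own law is untouched — but their subsequent
events are booked separately, because in the coupled no-OPS arm those
users are dead. Replicate by replicate the coupled baseline marginals are
`fatal - tagged_fatal + averted` and `nonfatal - tagged_nonfatal -
averted`, so the paired direct effects are `averted - tagged_fatal`
(fatal reduction) and `averted + tagged_nonfatal` (nonfatal increase),
with all shared event noise cancelled: standard errors drop from several
events to a fraction of an event at a few hundred replicates.

*Treatment pairing (joint chain).* With no OPS the rings do not affect
the dynamics, so the two arms of a treatment-rate comparison are run as
one joint chain over the product state space (active, treatment, dead)^2:
while a person's two arm-states coincide, one shared draw drives both
arms (treatment entry by nested thinning — entrants in the baseline arm
are a subset of entrants in the raised arm); after divergence each side
follows its own hazards. Either marginal is exactly the corresponding
single-arm law, and the reported reductions are within-pair differences.

## Experiments

* `calibration_experiment()` — no-OPS baseline; replicate means of annual
  fatal/nonfatal events against the published 1,045 / 3,933.
* `capacity_sweep()` — capacities 0-300 by 30 at in-OPS proportion 1;
  differences versus the no-OPS arm and the least-squares slope of fatal
  reduction per 30 stations (~6; under saturation the closed form is
  `30 * open_steps * p_f = 5.7`, the small surplus coming from revived
  users living to overdose again).
* `proportion_sweep()` — locates, for each capacity, the in-OPS overdose
  proportion at which the net change in annual nonfatal overdoses crosses
  zero (grid step 0.05, linear interpolation). The default `"paired"`
  estimator exploits a structural fact: with no treatment referral, the
  in-OPS overdose outcome does not feed back on the trajectory, so a
  single proportion-1 run per capacity supports every grid point by exact
  binomial thinning of its in-OPS overdose events against the in-run
  counterfactual. This is common-random-numbers coupling taken to its
  maximum; it shrinks the Monte-Carlo error of the crossing by roughly
  two orders of magnitude, which matters because at capacity 30 the
  displaced-overdose signal (~21 events/yr) is a third of one replicate's
  standard deviation. Its one approximation is the survivor-feedback term
  (revived users overdosing again), which shifts the crossing by under a
  percentage point. The `"independent"` method differences separate runs,
  as the published sweep was computed, and is provided for validation.
  The saturation crossing is `p_nf / (p_f + p_nf) = 0.790` per-use
  (0.786 on annual rates) — a 21% in-OPS overdose-rate reduction, inside
  the published 20-30% break-even band.
* `treatment_sweep()` — raises annual treatment entry (relapse fixed at
  50%) with *all arms initialized at the 15% equilibrium*: the published
  effect sizes (90/23 fewer events at 20%, 181/47 at 25%) match the
  one-year relaxation from the baseline equilibrium, not a re-equilibrated
  steady state, so that is the default (`init_rate`).
* `spatial_attribution()` — cumulative revived-in-OPS shares by distance
  next to population shares; since visit probability decays with
  distance, revived shares dominate population shares at every radius.

## Problem sizes and tolerances

The packaged tests and the acceptance script run the baseline scenarios
at 50-400 replicates per arm rather than the 3,000 used for the original
figures; Monte-Carlo standard errors at those sizes are a few events per
year, and all stochastic checks use 3-standard-error tolerances. Unit
tests exercise the same machinery on scaled-down cohorts (hundreds to a
few thousand users, 5-60 day horizons) with inflated overdose rates so
that distributional comparisons have power at that scale.

## Limitations

The model shares the original framework's simplifications: a single site,
no circadian structure within the day, no disease transmission, no memory
of OPS exposure, and a user population distributed like observed
overdoses. The synthetic far-field spatial distribution and the joint
demographic structure are assumptions, constrained only by the printed
marginals; conclusions that depend on unpublished per-ring numbers
(e.g. exact revival attribution percentages) are checked only as
qualitative dominance properties. Reported overdose counts likely
undercount true events, so, as in the original analysis, effect sizes are
conservative lower bounds.
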