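---
title: "Modelling the cost-effectiveness of mobile stroke unit services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of mobile stroke unit services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msucea)
```

## The decision problem

Mobile stroke units (MSUs) are CT-equipped ambulances that bring stroke
imaging and intravenous thrombolysis to the patient, shortening the
onset-to-treatment interval and shifting the distribution of 90-day
disability (modified Rankin Scale, mRS) toward better outcomes. They are
expensive to buy and to staff, and their value depends heavily on local
configuration: how many people the catchment zone contains, how many hours a
day and days a week the unit operates, and how many true strokes the service
fails to reach. `msucea` implements a decision-analytic model that chains
four components to quantify these trade-offs for urban German settings:

1. a **case-volume model**: catchment incidence, an attrition cascade of
   missed cases, and the service schedule determine how many patients the
   MSU manages per year;
2. a **programme cost model**: annualized investment, running and staffing
   costs, divided by the managed case load;
3. a **5-year Markov cohort model** of post-stroke outcomes under
   conventional versus MSU-based care, accruing discounted quality-adjusted
   life years (QALYs) and costs;
4. an **incremental synthesis**: incremental cost-effectiveness ratio
   (ICER = ΔC/ΔE) and net monetary benefit (NMB = λ·ΔE − ΔC) at a
   willingness-to-pay threshold λ of €47,901 per QALY (1× German GDP per
   capita).

The whole pipeline is deterministic (a cohort expectation); uncertainty is
handled by deterministic and probabilistic sensitivity analysis on top.

```{r base-case}
fit <- msu_cea()        # 750,000 inhabitants, 8 h / 7 days
fit
```

## Case volume

Annual incident cases per diagnosis are `population × incidence / 100,000`
for ischemic stroke, hemorrhagic stroke, TIA and stroke mimics. Cases are
then thinned by, in order: the fraction never contacting emergency services
in time, the fraction not fulfilling MSU alarming criteria, the service
window, dispatcher misidentification, and logistic misses. Counts remain
real-valued expectations throughout; nothing is rounded before reporting.

**Service window.** The window coverage is
`(operational days / 365) × (circadian mass inside the daily window)`.
Operational days are scheduled days capped at 300 per year; under that cap
6-day and 7-day schedules coincide, which is why the 12-mode grid
{8, 12, 16, 24} h × {5, 6, 7} d contains duplicate columns. The daily window
is contiguous from a configurable start hour (default 07:00, a first-class
knob because it interacts with the circadian profile; wrap-around past
midnight is supported). The shipped circadian profile is a morning-peaked
24-hour weight vector (assumed provenance): 51.7% of onsets fall in the
default 8-hour window, 70.5% in 12 hours, 84.5% in 16 hours.

**Miss model.** The dispatcher miss (37%) and the logistic miss
(8% + 2.5 percentage points per 100,000 inhabitants, reflecting simultaneous
stroke events a single unit cannot serve) are combined **additively** by
default — as mutually exclusive causes — because the additive rule exactly
reproduces the reference analysis's published missed-case percentages across
catchment sizes (e.g. 55.0% at 400,000, 70.0% at 1,000,000). An independent
(multiplicative) combination is available via `miss_model =
"multiplicative"`; the functional form of the logistic rule is exposed as
base/slope parameters so alternative readings are one-line changes.

**Coverage.** Published coverage figures and missed-case percentages use
different denominators that cannot be reconciled from aggregate numbers
alone. We define `coverage_fraction` as managed IS patients over all
incident IS in the catchment (default), with the dispatch-eligible
denominator selectable.

## Programme costs

Investment is straight-line depreciation of the capital items (vehicle, CT,
other equipment; €1.18M total) over 6 years, with no interest on capital.
Running costs are a fixed annual amount. Staffing scales with staffed hours
(hours/day × operational days) for the on-board team — paramedic,
neurologist, radiology technician — plus fixed annual allocations for a
remote radiologist (not exclusive to the MSU) and a 50% physician project
manager, all multiplied by a 22% administration overhead. Training can be
added as a fixed annual amount (default 0, i.e. folded into the role rates).
With teleneurology the on-board neurologist's hourly cost is replaced by a
cheaper remote-assessment rate; in the base case this lowers the per-IS
deployment cost by about 11%.

Per-patient deployment cost is the annual programme cost divided by the
managed count (IS-only or all-managed denominator), plus an optional
variable cost per deployment (default 0; the rendezvous ambulance that
transports the patient would have been dispatched under either strategy, so
its cost enters the acute-care costs of both arms symmetrically).

## The Markov cohort model

Only ischemic stroke patients are followed long-term; MSU benefit is
modelled solely through their 90-day mRS entry distribution. States are
mRS 0–5 plus absorbing death. Cycle 0 applies the entry distribution and the
acute admission cost (90-day death mass enters the dead state before any
annual accrual). Each annual cycle t = 1…5 then applies, per current state
k:

- **mortality first**: an annual mRS-specific death probability;
- **recurrence among survivors**: a time-dependent annual recurrence
  probability; a recurrent stroke redistributes the patient to a state at
  least as bad as k (or death), using the strategy's entry distribution
  truncated to states ≥ k and renormalized — the minimal rule consistent
  with "same or deteriorated" outcomes, and swappable;
- the remainder stays in k.

Utilities (a German mRS value set, assumed provenance) and long-term annual
costs accrue on the end-of-cycle occupancy, discounted at 3%/year as
`(1.03)^(−t)`; recurrent events are charged an acute cost at the destination
level. A half-cycle correction (trapezoid accrual) is available as a switch
and off by default, so the closed forms hold exactly: with full utility and
no events the 5-year QALY total is the annuity `Σ 1.03^(−t) = 4.5797`, and
with zero discounting it is 5.0.

Non-IS managed patients (TIA, hemorrhage, mimics) contribute diagnosis-
specific acute costs and a fixed utility stream, identical across
strategies, so they dilute per-dispatched-patient averages but cancel in the
increments: ΔE per dispatched patient equals the IS share times the per-IS
QALY gain.

Long-term costs take the healthcare perspective (stroke-induced extra
hospitalization days) or the societal perspective (additionally
insurance-covered nursing, family-covered nursing, and productivity losses
under the human capital approach — gross wage × employment rate × lost work
ability, applied only below a retirement cutoff of 67; at the cohort mean
age of 72.5 this component is structurally zero, which we keep configurable
rather than dropping, since the cutoff and age are both inputs).

## Incremental synthesis

`icer()` reports ΔC, ΔE and the ratio, but flags dominance (cheaper & more
effective, or dearer & less effective) instead of reporting a misleading
ratio, and treats ΔE = 0 as an undefined ratio with NMB still defined.
Internally everything is full precision; rounding (nearest €, 2-decimal
QALYs) happens only in the reporting layer — published tables rounded this
way generally cannot reproduce their own ICERs by back-division, which is
why the package never does arithmetic on rounded values.

## Parameters, provenance and calibration

Every input lives in one typed registry (`msu_parameters()`), serializable
to YAML (`inst/extdata/base_case.yaml`) and validated against a shipped
schema: probabilities in [0,1], simplexes summing to 1, costs nonnegative,
missing keys reported by name. Each parameter carries a provenance tag:
`paper` for the constants printed in the reference analysis's main text
(discounting, miss rates, overhead, depreciation, WTP, base population,
operating constraints), `assumed` for the shipped defaults standing in for
its non-public supplementary tables (incidence, mRS distributions,
utilities, mortality/recurrence, cost line items), and `user` after an
override. `provenance_report()` lists them.

The assumed set was fixed once, from German epidemiology and MSU programme
literature, and anchored to aggregates the reference analysis does print:
total capital ≈ €1.18M; the base-case cost shares (15.8% investment, 37.6%
running, 46.6% staffing); 124 managed IS patients/year at 750,000
inhabitants and 8 h/7 d (via the MSU-criteria rate); and the ≈11% relative
teleneurology saving (via the remote-assessment rate). Those anchors make
the deployment costs per IS patient (≈ €10,047) and per managed patient
(≈ €3,620) emerge from the same arithmetic. Downstream outputs (ICERs,
PSA fractions) are *not* anchored; under the shipped defaults the base case
yields an ICER of roughly €40,000/QALY (healthcare) and €23,000/QALY
(societal), the right order of magnitude for urban German MSU services, and
all qualitative orderings of the reference analysis hold: ICER falls with
catchment size, the 16 h/7 d mode is the most and 8 h/5 d the least
cost-effective of the 12-mode grid, and NMB falls as more strokes are
missed.

## Sensitivity analysis

`scenario_grid()` evaluates the full pipeline per mode × population cell
(zero-managed cells are flagged, not fatal). `two_way_dsa()` varies the
total missed-stroke fraction against the operating mode and reports annual
programme-scale NMB, which keeps the all-missed limit well defined (NMB =
−programme cost). `run_psa()` re-samples every parameter with an attached
distribution — beta for probabilities (mean-preserving, effective sample
size), gamma for costs (mean-preserving, CV), Dirichlet for the mRS entry
distributions — and re-runs the deterministic pipeline per iteration
(standard cohort-PSA practice: no within-cohort sampling). Parameters are
sampled independently; a correlation hook would slot into
`sample_parameters()` but none is shipped because no dependence structure is
asserted by the sources. The acceptability curve reports the fraction of
iterations with NMB ≥ 0 over a WTP grid of €0–150,000 in €1,000 steps. The
distribution families are a declared assumption; the effective sample sizes
(60–200) give coefficients of variation of a few percent to ~10%, typical
for second-order uncertainty in published stroke models.

```{r psa, eval = FALSE}
psa <- run_psa(msu_parameters(), n = 10000, seed = 1)
psa
plot(psa, "healthcare")
```

## Validation oracles

Two independent simulators check the analytic model against its own
assumptions:

- **Discrete-event call stream** (`simulate_calls`, `des_coverage`):
  nonhomogeneous Poisson arrivals generated by thinning (exact for the
  piecewise-constant hourly intensity), replayed against the service
  calendar, the dispatcher flag, and a single MSU that is busy for a
  configurable service time (default 90 minutes) after each accepted call.
  With stationary arrivals the blocked fraction must converge to the
  single-server Erlang loss probability a/(1+a), a = λs — the tests verify
  this over a 50-year stream — and with the service time at zero the
  empirical coverage must match the analytic cascade. The DES quantifies
  what blocking a single unit actually produces; whether the linear
  +2.5 pp/100,000 rule matches an underlying queuing argument is left as a
  side-by-side comparison, not asserted.
- **Patient-level microsimulation** (`microsimulate`): simulates individual
  trajectories under exactly the process the cohort model takes
  expectations over (death first, then recurrence with same-or-worse
  redistribution, identical accrual and discounting). Cohort and
  microsimulation means must agree within 3 Monte-Carlo standard errors;
  the acceptance suite runs this at n = 100,000 patients.

What the synthetic call generator emulates: annual rates, diagnosis mix,
circadian structure, dispatcher identification, single-unit blocking. What
it does not: geography and travel times, multi-vehicle fleets, day-to-day
rate heterogeneity, seasonality, and correlated call clusters beyond
Poisson. Passing oracle tests therefore shows internal consistency of the
analytic model, not fidelity of the assumed inputs to any particular city.

## Numerical choices and problem sizes

Tolerances: simplex and row-stochasticity checks at 1e-9 (1e-6 after YAML
round trips); closed-form identities at 1e-12; stochastic agreement at 3
Monte-Carlo standard errors (4 for seed-to-seed comparisons). Degenerate
inputs: zero managed patients is an error for per-patient division, a
flagged row in grids, and the −programme-cost limit in the DSA; PSA
sampling keeps structurally degenerate values (probability 0/1, cost 0)
fixed. Default problem sizes — 10,000 PSA iterations, 100,000
microsimulated patients, 50-year validation streams — were chosen so the
Monte-Carlo error is far below every difference of interest (ce-fraction SE
≈ 0.5 pp at n = 10,000) while the full suite runs in well under a minute of
compute.

## Known limitations

- Outcome benefit is restricted to ischemic stroke; potential MSU benefits
  for hemorrhage triage or endovascular-therapy routing are excluded by
  design, making the model conservative.
- The 5-year horizon forgoes lifetime extrapolation; QALY gains are
  bounded by the annuity of the horizon.
- The shipped `assumed` parameter set is a documented stand-in, not a
  transcription of any trial's record-level data; users with access to the
  primary sources should supply their own file
  (`read_msu_parameters("your.yaml")`) — every headline number will then be
  recomputed from it.
- A single MSU per catchment; fleet dispatching is out of scope.
- Urban settings only; travel-time and rural geography are not modelled.
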