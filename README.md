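# msucea

Decision-analytic cost-effectiveness modelling of **mobile stroke unit
(MSU)** services — CT-equipped ambulances that bring pre-hospital stroke
imaging and intravenous thrombolysis to the patient — for urban catchment
zones in the German healthcare system.

The package is written for health economists and stroke-service planners
who need to answer configuration questions before committing to an MSU
programme: how large must the catchment be, which operating hours pay off,
and how sensitive is the answer to missed strokes and parameter
uncertainty.

## The model

Four chained components, all exposed as plain R functions and bundled by
`msu_cea()`:

1. **Case volume.** Annual incident cases per diagnosis
   (`population × incidence / 100,000`) are thinned by an attrition
   cascade — no EMS contact, alarming criteria not met, outside the service
   window, dispatcher misidentification (37%), logistic misses
   (8% + 2.5 pp per 100,000 inhabitants from simultaneous events) — to the
   patients the MSU actually manages. The service window combines an
   operational-day fraction (scheduled days capped at 300/year) with the
   circadian mass of stroke onsets inside the daily window.
2. **Programme costs.** Straight-line 6-year depreciation of capital,
   fixed running costs, and staffing that scales with staffed hours
   (paramedic, neurologist, radiology technician, plus a remote radiologist
   and a 50% project manager) under a 22% administration overhead; per-patient
   deployment cost divides the annual total by the managed case load.
3. **Markov cohort model.** Ischemic stroke patients enter at their
   strategy-specific 90-day modified Rankin Scale (mRS) distribution and are
   followed for 5 annual cycles through states mRS 0–5 and death, with
   mRS-specific mortality, time-dependent recurrence redistributing only to
   same-or-worse states, mRS utilities, and acute plus long-term costs
   (healthcare or societal perspective), all discounted at 3%/year.
4. **Incremental synthesis.** ΔC, ΔE, the incremental cost-effectiveness
   ratio ICER = ΔC/ΔE with dominance handling, and net monetary benefit
   NMB = λ·ΔE − ΔC at λ = €47,901 per QALY (1× GDP per capita).

Scenario grids over operating modes ({8, 12, 16, 24} h × {5, 6, 7} d) and
catchment sizes, a two-way deterministic sensitivity analysis over the
missed-stroke fraction, and a 10,000-iteration probabilistic sensitivity
analysis with cost-effectiveness acceptability curves sit on top. Two
independent oracles — a discrete-event simulator of time-stamped stroke
calls (Erlang-loss blocking of the single unit) and a patient-level
microsimulation — validate the analytic cascade and the cohort model.

All model inputs live in a typed, YAML-serializable parameter registry with
provenance tags (`paper` / `assumed` / `user`) and per-parameter PSA
distributions; see `msu_parameters()`, `provenance_report()` and the
shipped `inst/extdata/base_case.yaml`.

## Worked example

```r
library(msucea)
fit <- msu_cea()       # base case: 750,000 inhabitants, 8 h / 7 days
fit
#> MSU cost-effectiveness analysis: mode 8x7, population 750,000
#>   managed IS patients/year: 124.0 (all diagnoses: 344.1)
#>   deployment cost: EUR 10,047 per IS patient, EUR 3,620 per managed patient
#> Incremental analysis (healthcare): dC = EUR 2,933, dE = 0.0729 QALYs, ICER = EUR 40,218/QALY, NMB(EUR 47,901) = EUR 560
#> Incremental analysis (societal): dC = EUR 1,672, dE = 0.0729 QALYs, ICER = EUR 22,923/QALY, NMB(EUR 47,901) = EUR 1,822
```

Reading this: of ~1,500 annual ischemic strokes in the catchment, the 8 h/7 d
service reaches 124; spreading the €1.25M annual programme cost over all 344
managed patients costs €3,620 per deployment (€10,047 per ischemic stroke
patient). MSU care adds 0.073 discounted QALYs and €2,933 (healthcare
perspective) per dispatched patient over 5 years — an ICER of €40,218/QALY,
below the €47,901 willingness-to-pay threshold, hence the positive net
monetary benefit.

Catchment size is the dominant lever:

```r
scenario_grid(msu_parameters(), list("8x7"), c(300000, 500000, 750000, 1000000))
#>  mode population managed_is deployment_cost_is icer_healthcare icer_societal
#>   8x7     300000      65.00              19168           85291         67996
#>   8x7     500000      96.93              12854           54090         36794
#>   8x7     750000     124.01              10047           40218         22923
#>   8x7    1000000     136.84               9105           35564         18269
```

Small catchments concentrate the fixed programme cost on few patients and
push the ICER far above the threshold; from roughly 500,000–700,000
inhabitants upward the service becomes cost-effective. `summary(fit)` shows
the cost composition and the full case funnel, `simulate(fit, nsim, seed)`
runs the PSA for a fitted configuration, and `plot()` methods draw the cost
composition, mode grids, the cost-effectiveness plane and acceptability
curves.

A thin command-line wrapper over the same functions ships at
`inst/cli/msucea.R` (subcommands `base-case`, `grid`, `dsa`, `psa`,
`des-validate`).

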