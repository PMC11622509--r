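Package: msucea
Title: Cost-Effectiveness Modelling of Mobile Stroke Unit Services
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Health-economic decision modelling of mobile stroke unit (MSU)
    services in urban settings: a case-volume model converting catchment
    population, stroke incidence, a missed-case cascade and the service
    schedule into annual patient counts; an MSU programme cost model
    (investment, running and staffing costs with overhead and straight-line
    depreciation); a 5-year annual-cycle Markov cohort model of post-stroke
    outcomes on the modified Rankin Scale with recurrence, mortality, utility
    and cost accrual under discounting; incremental cost-effectiveness
    synthesis (ICER, net monetary benefit, dominance handling); scenario grids
    over operating modes and catchment sizes, two-way deterministic
    sensitivity analysis and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves; and two independent validation
    oracles, a discrete-event simulator of time-stamped stroke calls and a
    patient-level microsimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
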