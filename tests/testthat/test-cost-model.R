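test_that("single-component programme cost yields a 100% share", {
  p <- msu_parameters(overrides = list(
    capital_vehicle = 600000, capital_ct = 0, capital_equipment = 0,
    running_annual = 0, paramedic_hourly = 0, neurologist_hourly = 0,
    radiology_tech_hourly = 0, remote_radiologist_annual = 0,
    project_manager_annual = 0, training_annual = 0))
  pc <- annual_program_cost(p, operating_mode(8, 7))
  expect_equal(pc$investment, 100000)    # 600,000 over 6 years
  expect_equal(unname(pc$shares["investment"]), 1)
})

test_that("staffing scales linearly with staffed hours", {
  pc8 <- annual_program_cost(base_params, operating_mode(8, 7))
  pc16 <- annual_program_cost(base_params, operating_mode(16, 7))
  fixed <- (param_value(base_params, "remote_radiologist_annual") +
            param_value(base_params, "project_manager_annual") * 0.5) *
           (1 + param_value(base_params, "overhead"))
  expect_equal(pc16$staffing - fixed, 2 * (pc8$staffing - fixed),
               tolerance = 1e-9)
  # investment and running are mode-independent
  expect_equal(pc8$investment, pc16$investment)
  expect_equal(pc8$running, pc16$running)
})

test_that("cost shares sum to one for arbitrary inputs", {
  set.seed(11)
  for (i in 1:20) {
    p <- msu_parameters(overrides = list(
      capital_vehicle = runif(1, 0, 1e6), running_annual = runif(1, 0, 1e6),
      neurologist_hourly = runif(1, 0, 200)))
    pc <- annual_program_cost(p, operating_mode(sample(c(8, 12, 16, 24), 1),
                                                sample(c(5, 6, 7), 1)))
    expect_equal(sum(pc$shares), 1, tolerance = 1e-9)
  }
})

test_that("teleneurology lowers the per-patient MSU cost", {
  m <- operating_mode(8, 7)
  cc <- build_cascade(base_params, m)
  on_board <- annual_program_cost(base_params, m, teleneurology = FALSE)
  tele <- annual_program_cost(base_params, m, teleneurology = TRUE)
  expect_lt(tele$total, on_board$total)
  expect_lt(per_patient_deployment_cost(tele, cc, "is"),
            per_patient_deployment_cost(on_board, cc, "is"))
})

test_that("deployment cost is annual cost over managed count plus variable cost", {
  cc <- build_cascade(base_params, operating_mode(8, 7))
  n_is <- unname(cc$managed["ischemic"])
  expect_equal(per_patient_deployment_cost(1e6, cc, "is"), 1e6 / n_is)
  # conservation: per-patient x n = annual + n x variable
  pp <- per_patient_deployment_cost(1e6, cc, "is", variable_cost = 120)
  expect_equal(pp * n_is, 1e6 + n_is * 120, tolerance = 1e-9)
  # IS-only denominator is the larger per-patient cost
  expect_gte(per_patient_deployment_cost(1e6, cc, "is"),
             per_patient_deployment_cost(1e6, cc, "all"))
  # strictly decreasing in managed count (within the modelled catchment range)
  cc_big <- build_cascade(base_params, operating_mode(8, 7), population = 1e6)
  expect_lt(per_patient_deployment_cost(1e6, cc_big, "is"),
            per_patient_deployment_cost(1e6, cc, "is"))
  # undefined at zero managed patients
  p0 <- msu_parameters(overrides = list(ems_contact_rate = 0))
  cc0 <- build_cascade(p0, operating_mode(8, 7))
  expect_error(per_patient_deployment_cost(1e6, cc0, "is"), "undefined")
})

test_that("acute-care costs apply strategy-specific short-term components", {
  # MSU never includes the secondary transfer
  p <- msu_parameters(overrides = list(secondary_transfer_prob = 0.4,
                                       secondary_transfer_cost = 1000))
  gap <- acute_care_cost(p, 2, "conventional") - acute_care_cost(p, 2, "msu")
  expect_equal(gap, param_value(p, "conventional_transport_cost") + 0.4 * 1000 -
                 param_value(p, "msu_transport_cost"))
  # transfer probability 0: arms differ only by the transport components
  p0 <- msu_parameters(overrides = list(secondary_transfer_prob = 0))
  expect_equal(acute_care_cost(p0, 3, "conventional") - acute_care_cost(p0, 3, "msu"),
               param_value(p0, "conventional_transport_cost") -
                 param_value(p0, "msu_transport_cost"))
  # shipped defaults: acute cost nondecreasing in disability over mRS 0..5
  ac <- acute_care_cost(base_params, 0:5, "msu")
  expect_true(all(diff(ac) >= 0))
  expect_error(acute_care_cost(base_params, 7, "msu"), "mRS")
})

test_that("long-term costs: societal adds nursing and productivity to healthcare", {
  hc <- longterm_annual_cost(base_params, 0:5, "healthcare")
  soc <- longterm_annual_cost(base_params, 0:5, "societal")
  expect_true(all(soc >= hc))
  expect_equal(hc[1], 0)                 # mRS 0: no extra hospital days
  expect_true(all(diff(hc) >= 0))        # nondecreasing in mRS (shipped defaults)
  expect_true(all(diff(soc) >= 0))
  # additivity by construction
  nursing <- param_value(base_params, "lt_nursing_insurance_by_mrs") +
    param_value(base_params, "lt_nursing_family_by_mrs")
  expect_equal(soc, hc + unname(nursing))   # no productivity at mean age 72.5
  # productivity applies only below the retirement cutoff
  soc_young <- longterm_annual_cost(base_params, 0:5, "societal", age = 55)
  wage_term <- param_value(base_params, "gross_annual_wage") *
    param_value(base_params, "employment_rate") *
    (1 - param_value(base_params, "ability_to_work_by_mrs"))
  expect_equal(soc_young, soc + unname(wage_term))
})

test_that("base-case cost composition matches the anchored aggregates", {
  pc <- annual_program_cost(base_params, operating_mode(8, 7))
  expect_equal(100 * unname(pc$shares), c(15.8, 37.6, 46.6), tolerance = 0.01)
  cc <- build_cascade(base_params, operating_mode(8, 7))
  expect_equal(per_patient_deployment_cost(pc, cc, "is"), 10040, tolerance = 0.01)
  expect_equal(per_patient_deployment_cost(pc, cc, "all"), 3620, tolerance = 0.01)
})
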