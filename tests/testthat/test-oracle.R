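test_that("simulated call stream matches its configured Poisson rate", {
  cfg <- des_config(c(ischemic = 365), uniform_circadian(),
                    mode = operating_mode(24, 7, max_operational_days = 365))
  st <- simulate_calls(cfg, years = 10, seed = 2)
  gaps <- diff(st$time_days)
  expect_lt(abs(mean(gaps) - 1), 3 / sqrt(length(gaps)))   # exponential mean 1 day
  expect_true(all(diff(st$time_days) >= 0))                # sorted
  expect_true(all(st$time_days >= 0 & st$time_days <= 10 * 365))
})

test_that("hours with zero circadian weight receive no events", {
  w <- c(rep(0, 7), rep(1 / 17, 17))
  cfg <- des_config(c(ischemic = 500), circadian_profile(w))
  st <- simulate_calls(cfg, years = 5, seed = 3)
  expect_false(any(st$hour < 7))
  expect_gt(nrow(st), 0)
})

test_that("the hourly histogram reproduces the circadian profile", {
  circ <- circadian_profile(param_value(base_params, "circadian_weights"))
  cfg <- des_config(c(ischemic = 600, mimic = 400), circ)
  st <- simulate_calls(cfg, years = 50, seed = 4)
  obs <- tabulate(st$hour + 1, nbins = 24)
  gof <- suppressWarnings(stats::chisq.test(obs, p = circ$weights))
  expect_gt(gof$p.value, 0.01)
  # diagnosis mix matches configuration within sampling error
  p_is <- mean(st$diagnosis == "ischemic")
  expect_lt(abs(p_is - 0.6), 3 * sqrt(0.6 * 0.4 / nrow(st)))
})

test_that("blocked fraction converges to the single-server Erlang loss formula", {
  # stationary arrivals 2/day, 2 h occupation: offered load a = 1/6,
  # blocking a/(1+a) = 1/7
  cfg <- des_config(c(ischemic = 2 * 365), uniform_circadian(),
                    service_time_hours = 2,
                    mode = operating_mode(24, 7, max_operational_days = 365))
  st <- simulate_calls(cfg, years = 50, seed = 5)
  cov <- des_coverage(st, cfg)
  expected <- erlang_b1(2, 2 / 24)
  expect_equal(expected, 1 / 7, tolerance = 1e-12)
  n <- sum(cov$eligible_flags)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(cov$blocked_fraction - expected), 3 * se)
})

test_that("with no blocking the DES reproduces the analytic window and dispatcher attrition", {
  circ <- circadian_profile(param_value(base_params, "circadian_weights"))
  mode <- operating_mode(8, 7)
  rate <- c(ischemic = 1000)
  cfg <- des_config(rate, circ, service_time_hours = 0, mode = mode)
  st <- simulate_calls(cfg, years = 40, seed = 6, dispatcher_miss = 0.37)
  cov <- des_coverage(st, cfg)
  p_managed <- sum(cov$managed_flags) / nrow(st)
  p_expected <- window_coverage(mode, circ) * (1 - 0.37)
  se <- sqrt(p_expected * (1 - p_expected) / nrow(st))
  expect_lt(abs(p_managed - p_expected), 3 * se)
})

test_that("busier catchments lose more eligible calls to simultaneity", {
  circ <- circadian_profile(param_value(base_params, "circadian_weights"))
  blocked_at <- function(rate) {
    cfg <- des_config(c(ischemic = rate), circ, service_time_hours = 2,
                      mode = operating_mode(24, 7, max_operational_days = 365))
    des_coverage(simulate_calls(cfg, years = 30, seed = 7), cfg)$blocked_fraction
  }
  expect_gt(blocked_at(4000), blocked_at(1000))
})

test_that("microsimulation agrees with the cohort model within Monte Carlo error", {
  spec <- markov_spec(base_params, "conventional")
  cohort <- run_cohort(spec, base_params, "healthcare")
  micro <- microsimulate(spec, base_params, n = 20000, seed = 8,
                         perspective = "healthcare")
  expect_lt(abs(micro$qalys - cohort$qalys), 3 * micro$se_qalys)
  expect_lt(abs(micro$cost - cohort$cost), 3 * micro$se_cost)
})

test_that("forced mortality absorbs every simulated patient after one cycle", {
  p <- msu_parameters(overrides = list(mortality_by_mrs = rep(1, 6)))
  spec <- markov_spec(p)
  micro <- microsimulate(spec, p, n = 500, seed = 9)
  expect_equal(micro$qalys, 0)
  cohort <- run_cohort(spec, p)
  expect_equal(unname(cohort$trace["cycle1", "death"]), 1)
})

test_that("oracles are reproducible under a fixed seed", {
  cfg <- des_config(c(ischemic = 200), uniform_circadian())
  expect_identical(simulate_calls(cfg, 2, seed = 10),
                   simulate_calls(cfg, 2, seed = 10))
  spec <- markov_spec(base_params)
  expect_identical(microsimulate(spec, base_params, n = 200, seed = 11),
                   microsimulate(spec, base_params, n = 200, seed = 11))
})
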