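test_that("annual case counts follow the incidence definition", {
  inc <- c(ischemic = 200, hemorrhagic = 30, tia = 80, mimic = 150)
  expect_equal(unname(annual_cases(100000, inc)["ischemic"]), 200)
  expect_equal(unname(annual_cases(0, inc)), rep(0, 4))
  expect_equal(annual_cases(200000, inc), 2 * annual_cases(100000, inc))
})

test_that("window coverage handles full-day, uniform and weighted windows", {
  circ <- circadian_profile(param_value(base_params, "circadian_weights"))
  expect_equal(window_coverage(operating_mode(24, 7), circ), 300 / 365,
               tolerance = 1e-12)
  expect_equal(window_coverage(operating_mode(8, 7), uniform_circadian()),
               (300 / 365) * (8 / 24), tolerance = 1e-12)
  # profile with exactly 45% of mass inside an 8-h window from 07:00
  w <- c(rep(0.55 / 16, 7), rep(0.45 / 8, 8), rep(0.55 / 16, 9))
  expect_equal(window_coverage(operating_mode(8, 7), circadian_profile(w)),
               (300 / 365) * 0.45, tolerance = 1e-12)
})

test_that("windows wrapping past midnight are handled", {
  w <- param_value(base_params, "circadian_weights")
  m <- operating_mode(8, 7, window_start = 20)      # 20:00-04:00
  expected <- (300 / 365) * sum(w[c(21:24, 1:4)])
  expect_equal(window_coverage(m, circadian_profile(w)), expected,
               tolerance = 1e-12)
})

test_that("coverage is nondecreasing in hours per day and days per week", {
  circ <- circadian_profile(param_value(base_params, "circadian_weights"))
  for (d in c(5, 6, 7)) {
    wc <- vapply(c(8, 12, 16, 24),
                 function(h) window_coverage(operating_mode(h, d), circ), 0)
    expect_true(all(diff(wc) >= 0))
  }
  for (h in c(8, 12, 16, 24)) {
    wc <- vapply(c(5, 6, 7),
                 function(d) window_coverage(operating_mode(h, d), circ), 0)
    expect_true(all(diff(wc) >= 0))
  }
})

test_that("logistic miss follows the stated population rule", {
  expect_equal(logistic_miss(0), 0.08)
  expect_equal(logistic_miss(750000), 0.08 + 0.025 * 7.5)   # 0.2675
  expect_equal(logistic_miss(4e6), 1)                        # capped
  pops <- seq(0, 3e6, by = 1e5)
  expect_true(all(diff(logistic_miss(pops)) >= 0))
})

test_that("additive miss rule reproduces the published missed-case column", {
  # missed = dispatcher 0.37 + logistic base 0.08 + 0.025 per 100k
  expect_equal(miss_fraction(400000), 0.55)
  expect_equal(miss_fraction(500000), 0.575)
  expect_equal(miss_fraction(1e6), 0.70)
  expect_equal(miss_fraction(750000), 0.6375)
  # the multiplicative alternative is strictly smaller where both are < 1
  expect_lt(miss_fraction(750000, model = "multiplicative"),
            miss_fraction(750000, model = "additive"))
})

test_that("cascade is a lossless funnel when all attrition is switched off", {
  p <- msu_parameters(overrides = list(
    ems_contact_rate = 1, msu_criteria_rate = 1, dispatcher_miss = 0,
    logistic_miss_base = 0, logistic_miss_slope = 0))
  m <- operating_mode(24, 7, max_operational_days = 365)
  cc <- build_cascade(p, m)
  expect_equal(unname(cc$managed), unname(cc$stages["total_cases", ]),
               tolerance = 1e-12)
})

test_that("dispatcher miss alone removes exactly its fraction", {
  p <- msu_parameters(overrides = list(
    ems_contact_rate = 1, msu_criteria_rate = 1, dispatcher_miss = 0.37,
    logistic_miss_base = 0, logistic_miss_slope = 0))
  m <- operating_mode(24, 7, max_operational_days = 365)
  cc <- build_cascade(p, m)
  expect_equal(unname(cc$managed), 0.63 * unname(cc$stages["total_cases", ]),
               tolerance = 1e-12)
})

test_that("base case manages 124 ischemic stroke patients per year", {
  cc <- build_cascade(base_params, operating_mode(8, 7))
  expect_equal(unname(cc$managed["ischemic"]), 124, tolerance = 1e-3)
})

test_that("funnel monotonicity holds for random parameter draws", {
  set.seed(7)
  for (i in 1:25) {
    p <- random_cascade_params()
    m <- operating_mode(sample(c(8, 12, 16, 24), 1), sample(c(5, 6, 7), 1))
    for (mm in c("additive", "multiplicative")) {
      cc <- build_cascade(p, m, population = runif(1, 5e4, 3e6), miss_model = mm)
      expect_true(all(diff(cc$stages) <= 1e-9))     # each stage <= predecessor
      expect_true(all(cc$stages >= 0))
    }
  }
})

test_that("coverage fraction is monotone in schedule and retention", {
  cov_of <- function(p, h, d) build_cascade(p, operating_mode(h, d))$coverage_fraction
  expect_true(cov_of(base_params, 8, 7) <= cov_of(base_params, 12, 7))
  expect_true(cov_of(base_params, 12, 7) <= cov_of(base_params, 16, 7))
  expect_true(cov_of(base_params, 8, 5) <= cov_of(base_params, 8, 7))
  p_hi <- msu_parameters(overrides = list(ems_contact_rate = 0.9))
  expect_true(cov_of(base_params, 8, 7) <= cov_of(p_hi, 8, 7))
})

test_that("cascade exports a tidy data frame", {
  cc <- build_cascade(base_params, operating_mode(8, 7))
  df <- as.data.frame(cc)
  expect_named(df, c("diagnosis", "stage", "count"))
  expect_equal(nrow(df), 6 * 4)
})
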