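test_that("transition matrix reduces to the identity with no events", {
  spec <- markov_spec(quiet_params())
  M <- build_transition_matrix(spec, 1)
  expect_equal(unname(M), diag(7), tolerance = 1e-12)
})

test_that("mortality-only rows have exactly two outcomes", {
  p <- msu_parameters(overrides = list(
    mortality_by_mrs = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
    recurrence_by_year = rep(0, 5)))
  M <- build_transition_matrix(markov_spec(p), 1)
  for (k in 0:5) {
    expect_equal(unname(M[k + 1, k + 1]), 1 - (k + 1) / 10)
    expect_equal(unname(M[k + 1, 7]), (k + 1) / 10)
  }
})

test_that("recurrence redistributes only to same-or-worse states", {
  M <- build_transition_matrix(markov_spec(base_params, "msu"), 1)
  expect_equal(unname(M[3, 1]), 0)   # mRS2 -> mRS0 impossible
  expect_equal(unname(M[3, 2]), 0)   # mRS2 -> mRS1 impossible
  for (k in 0:5)
    expect_true(all(M[k + 1, seq_len(k)] == 0))
  # death is absorbing
  expect_equal(unname(M[7, ]), c(rep(0, 6), 1))
})

test_that("transition rows are stochastic for random specifications", {
  set.seed(23)
  for (i in 1:25) {
    p <- msu_parameters(overrides = list(
      mortality_by_mrs = runif(6, 0, 0.6),
      recurrence_by_year = runif(5, 0, 0.4)))
    spec <- markov_spec(p, sample(c("conventional", "msu"), 1))
    for (yr in 1:5) {
      M <- build_transition_matrix(spec, yr)
      expect_equal(unname(rowSums(M)), rep(1, 7), tolerance = 1e-9)
      expect_true(all(M >= 0))
    }
  }
})

test_that("discounted QALYs follow the annuity closed form without events", {
  p <- quiet_params(utilities_by_mrs = rep(1, 6))
  out <- run_cohort(markov_spec(p), p, entry = c(1, rep(0, 6)))
  expect_equal(out$qalys, sum((1 + 0.03)^-(1:5)), tolerance = 1e-12)
  # undiscounted horizon
  p0 <- quiet_params(utilities_by_mrs = rep(1, 6), discount_rate = 0)
  out0 <- run_cohort(markov_spec(p0), p0, entry = c(1, rep(0, 6)))
  expect_equal(out0$qalys, 5, tolerance = 1e-12)
})

test_that("an all-dead entry cohort accrues nothing downstream", {
  out <- run_cohort(markov_spec(base_params), base_params,
                    entry = c(rep(0, 6), 1))
  expect_equal(out$qalys, 0)
  expect_equal(unname(out$breakdown["longterm"]), 0)
  expect_equal(unname(out$breakdown["recurrence"]), 0)
})

test_that("state occupancy is conserved every cycle and QALYs respect the horizon", {
  for (strat in c("conventional", "msu")) {
    out <- run_cohort(markov_spec(base_params, strat), base_params, "societal")
    expect_equal(unname(rowSums(out$trace)), rep(1, 6), tolerance = 1e-9)
    expect_gte(out$qalys, 0)
    expect_lte(out$qalys, 5)
    expect_gte(out$cost, 0)
  }
})

test_that("identical entry distributions give exactly zero incremental QALYs", {
  conv <- param_value(base_params, "mrs_entry_conventional")
  p <- msu_parameters(overrides = list(mrs_entry_msu = unname(conv)))
  fit <- msu_cea(p)
  expect_identical(fit$cea$healthcare$delta_qalys, 0)
})

test_that("stochastically better entry distributions never lower QALYs", {
  set.seed(31)
  for (i in 1:20) {
    p <- msu_parameters(overrides = list(
      mortality_by_mrs = sort(runif(6, 0, 0.4)),
      recurrence_by_year = runif(5, 0, 0.2)))
    spec <- markov_spec(p, "conventional")
    base_entry <- unname(param_value(p, "mrs_entry_conventional"))
    better <- improve_entry(base_entry, amount = runif(1, 0.005, 0.04))
    q0 <- run_cohort(spec, p, entry = base_entry)$qalys
    q1 <- run_cohort(spec, p, entry = better)$qalys
    expect_gte(q1, q0)
  }
})

test_that("half-cycle correction changes accrual but not occupancy", {
  out <- run_cohort(markov_spec(base_params), base_params, half_cycle = TRUE)
  ref <- run_cohort(markov_spec(base_params), base_params, half_cycle = FALSE)
  expect_equal(out$trace, ref$trace)
  expect_gt(out$qalys, ref$qalys)   # start-of-cycle states are better on average
})

test_that("MSU entry distribution dominance yields positive incremental QALYs", {
  fit <- msu_cea(base_params)
  expect_gt(fit$cea$healthcare$delta_qalys, 0)
  # non-IS patients contribute identically: increment scales with the IS share
  cmp <- fit$outcomes$healthcare
  d_is <- cmp$is_outcomes$msu$qalys - cmp$is_outcomes$conventional$qalys
  expect_equal(fit$cea$healthcare$delta_qalys, cmp$is_share * d_is,
               tolerance = 1e-12)
})
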