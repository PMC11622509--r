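# shared fixtures: built in code, no stored data

base_params <- msu_parameters()

# parameter set with all transition events switched off
quiet_params <- function(...) {
  msu_parameters(overrides = c(list(
    mortality_by_mrs = rep(0, 6),
    recurrence_by_year = rep(0, 5)), list(...)))
}

# a random valid attrition/rate draw for property tests
random_cascade_params <- function() {
  msu_parameters(overrides = list(
    ems_contact_rate = runif(1),
    msu_criteria_rate = runif(1),
    dispatcher_miss = runif(1, 0, 0.9),
    logistic_miss_base = runif(1, 0, 0.3),
    logistic_miss_slope = runif(1, 0, 0.05),
    incidence_per_100k = runif(4, 10, 400)))
}

# an entry distribution stochastically better than `p` (mass moved from a
# worse state to a better one)
improve_entry <- function(p, amount = 0.02) {
  worse <- max(which(p[2:7] > amount)) + 1
  better <- sample.int(worse - 1, 1)
  p[worse] <- p[worse] - amount
  p[better] <- p[better] + amount
  p
}
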