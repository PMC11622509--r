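# Five-year annual-cycle Markov cohort model of post-stroke outcomes.
# States: mRS 0..5 (stable post-stroke disability) and death (absorbing).
# Each cycle a patient in mRS k can stay, suffer a recurrent stroke leading
# to the same or a worse disability level (or death), or die of other causes.

.states <- c(paste0("mRS", 0:5), "death")

#' Build a Markov specification for one strategy
#'
#' Bundles the transition inputs: per-mRS utilities and annual mortality,
#' time-dependent recurrence probabilities, and the recurrence redistribution
#' rule — the strategy's 90-day entry distribution truncated to states at or
#' worse than the current level (including death) and renormalized, the
#' minimal rule consistent with "same or deteriorated" outcomes.
#'
#' @param params an \code{msu_params} object
#' @param strategy \code{"conventional"} or \code{"msu"}
#' @return an object of class \code{markov_spec}
#' @export
markov_spec <- function(params, strategy = c("conventional", "msu")) {
  strategy <- match.arg(strategy)
  entry <- param_value(params,
                       if (strategy == "msu") "mrs_entry_msu" else "mrs_entry_conventional")
  structure(list(
    strategy = strategy,
    horizon = as.integer(param_value(params, "horizon_years")),
    discount_rate = param_value(params, "discount_rate"),
    utilities = param_value(params, "utilities_by_mrs"),
    mortality = param_value(params, "mortality_by_mrs"),
    recurrence = param_value(params, "recurrence_by_year"),
    redistribution = unname(entry)),
    class = "markov_spec")
}

# destination distribution over states k..5 and death after a recurrent
# stroke from mRS k: entry distribution truncated to >= k, renormalized
.recur_dest <- function(spec, k) {
  q <- spec$redistribution            # length 7: mRS0..5, death
  keep <- c(rep(FALSE, k), rep(TRUE, 6 - k), TRUE)
  qt <- q * keep
  s <- sum(qt)
  if (s <= 0) { qt <- numeric(7); qt[7] <- 1 } else qt <- qt / s
  qt
}

#' Annual transition matrix for one cycle
#'
#' Competing risks within a cycle: mortality first, recurrence among
#' survivors.  From mRS k: death receives mortality(k) plus the fatal share
#' of recurrences; recurrent non-fatal events move only to states at or worse
#' than k; the remainder stays at k.  Death is absorbing.
#'
#' @param spec a \code{markov_spec}
#' @param year cycle index in \code{1..horizon} (selects the recurrence rate)
#' @return a 7x7 row-stochastic matrix over mRS0..mRS5 and death
#' @examples
#' s <- markov_spec(msu_parameters())
#' rowSums(build_transition_matrix(s, 1))
#' @export
build_transition_matrix <- function(spec, year) {
  stopifnot(inherits(spec, "markov_spec"), year >= 1, year <= spec$horizon)
  r <- spec$recurrence[year]
  M <- matrix(0, 7, 7, dimnames = list(.states, .states))
  for (k in 0:5) {
    m <- spec$mortality[k + 1]
    q <- .recur_dest(spec, k)
    row <- (1 - m) * r * q
    row[k + 1] <- row[k + 1] + (1 - m) * (1 - r)
    row[7] <- row[7] + m
    M[k + 1, ] <- row
  }
  M[7, 7] <- 1
  if (any(abs(rowSums(M) - 1) > 1e-9))
    stop("transition matrix construction error: rows do not sum to 1")
  M
}

#' Run the cohort model for one strategy
#'
#' Cycle 0 applies the 90-day entry distribution and charges the acute-care
#' cost (death mass enters the absorbing state before any annual accrual).
#' Each subsequent cycle t = 1..horizon applies the year's transition matrix,
#' then accrues utility and long-term cost on the end-of-cycle occupancy,
#' discounted by (1 + r)^(-t); recurrent strokes are charged an acute-care
#' cost at the destination level in the cycle they occur.  An optional
#' half-cycle correction averages start- and end-of-cycle occupancy for the
#' accruals.
#'
#' @param spec a \code{markov_spec}
#' @param params an \code{msu_params} object
#' @param perspective \code{"healthcare"} or \code{"societal"}
#' @param entry optional length-7 probability vector over mRS0..5 and death
#'   replacing the strategy's 90-day distribution
#' @param half_cycle logical; apply a half-cycle correction (default FALSE,
#'   end-of-cycle accrual)
#' @return an object of class \code{strategy_outcome} with discounted average
#'   cost (euros), QALYs, the per-cycle occupancy trace, and a cost breakdown
#' @examples
#' out <- run_cohort(markov_spec(msu_parameters(), "msu"), msu_parameters())
#' out$qalys
#' @export
run_cohort <- function(spec, params, perspective = c("healthcare", "societal"),
                       entry = NULL, half_cycle = FALSE) {
  perspective <- match.arg(perspective)
  stopifnot(inherits(spec, "markov_spec"))
  if (is.null(entry)) entry <- spec$redistribution
  entry <- as.numeric(entry)
  if (length(entry) != 7 || any(entry < 0) || abs(sum(entry) - 1) > 1e-9)
    stop("entry must be a length-7 probability vector over mRS0..5 and death")

  disc <- (1 + spec$discount_rate)^-(seq_len(spec$horizon))
  u <- c(spec$utilities, 0)                       # death utility 0
  lt <- c(longterm_annual_cost(params, 0:5, perspective), 0)
  acute_recur <- c(param_value(params, "acute_cost_by_mrs"))  # by destination state

  x <- entry
  trace <- matrix(NA_real_, spec$horizon + 1, 7,
                  dimnames = list(paste0("cycle", 0:spec$horizon), .states))
  trace[1, ] <- x
  acute0 <- sum(entry * acute_care_cost(params, 0:6, spec$strategy))
  qalys <- 0; lt_cost <- 0; recur_cost <- 0
  for (t in seq_len(spec$horizon)) {
    M <- build_transition_matrix(spec, t)
    x_new <- as.vector(x %*% M)
    # expected recurrence mass and its acute cost by destination
    r <- spec$recurrence[t]
    for (k in 0:5) {
      mass <- x[k + 1] * (1 - spec$mortality[k + 1]) * r
      if (mass > 0)
        recur_cost <- recur_cost + mass * sum(.recur_dest(spec, k) * acute_recur) * disc[t]
    }
    accr <- if (half_cycle) (x + x_new) / 2 else x_new
    qalys <- qalys + sum(accr * u) * disc[t]
    lt_cost <- lt_cost + sum(accr * lt) * disc[t]
    x <- x_new
    trace[t + 1, ] <- x
  }
  structure(list(strategy = spec$strategy, perspective = perspective,
                 cost = acute0 + lt_cost + recur_cost, qalys = qalys,
                 breakdown = c(acute = acute0, longterm = lt_cost,
                               recurrence = recur_cost),
                 trace = trace, half_cycle = half_cycle),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("Strategy '%s' (%s perspective): discounted cost EUR %s, QALYs %.3f\n",
              x$strategy, x$perspective,
              format(round(x$cost), big.mark = ","), x$qalys))
  invisible(x)
}

#' Compare conventional and MSU strategies per dispatched patient
#'
#' Ischemic stroke patients receive strategy-specific 90-day entry
#' distributions and the full 5-year follow-up; other managed patients (TIA,
#' hemorrhagic stroke, mimic) contribute identical outcomes across strategies
#' — acute costs by diagnosis and a fixed utility stream — and differ only in
#' short-term cost.  Averages per dispatched patient weight the diagnoses by
#' the cascade's managed counts; the MSU strategy additionally carries the
#' per-patient deployment cost (all-managed denominator).
#'
#' @param params an \code{msu_params} object
#' @param cascade a \code{case_cascade}
#' @param program annual programme cost list from \code{annual_program_cost}
#' @param perspective \code{"healthcare"} or \code{"societal"}
#' @param half_cycle passed to \code{run_cohort}
#' @return list with per-dispatched-patient \code{conventional} and
#'   \code{msu} outcomes (cost, qalys), the underlying per-IS
#'   \code{strategy_outcome}s, and the deployment cost
#' @export
compare_strategies <- function(params, cascade, program,
                               perspective = c("healthcare", "societal"),
                               half_cycle = FALSE) {
  perspective <- match.arg(perspective)
  stopifnot(inherits(cascade, "case_cascade"))
  w <- cascade$managed / cascade$managed_total
  is_conv <- run_cohort(markov_spec(params, "conventional"), params,
                        perspective, half_cycle = half_cycle)
  is_msu <- run_cohort(markov_spec(params, "msu"), params,
                       perspective, half_cycle = half_cycle)

  # non-IS patients: identical downstream across strategies
  nonis_acute <- c(hemorrhagic = param_value(params, "acute_cost_hemorrhagic"),
                   tia = param_value(params, "acute_cost_tia"),
                   mimic = param_value(params, "acute_cost_mimic"))
  disc <- (1 + param_value(params, "discount_rate"))^-(seq_len(param_value(params, "horizon_years")))
  nonis_qalys <- param_value(params, "nonis_utility") * sum(disc)

  deploy <- per_patient_deployment_cost(program, cascade, denominator = "all",
                                        variable_cost = param_value(params, "deployment_variable_cost"))

  avg <- function(is_out, msu_arm) {
    cost <- w["ischemic"] * is_out$cost +
      sum(w[names(nonis_acute)] * nonis_acute) +
      if (msu_arm) deploy else 0
    qalys <- w["ischemic"] * is_out$qalys + (1 - w["ischemic"]) * nonis_qalys
    list(cost = unname(cost), qalys = unname(qalys))
  }
  list(conventional = avg(is_conv, FALSE),
       msu = avg(is_msu, TRUE),
       is_outcomes = list(conventional = is_conv, msu = is_msu),
       deployment_cost_per_managed = deploy,
       is_share = unname(w["ischemic"]),
       perspective = perspective)
}
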