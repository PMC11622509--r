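# Independent validation oracles.
# (a) A discrete-event simulator of time-stamped stroke calls: nonhomogeneous
#     Poisson arrivals with a circadian intensity, a single MSU with a finite
#     occupation time per deployment (an Erlang loss system), a service
#     window and operational-day calendar, and dispatcher identification.
# (b) A patient-level microsimulation of the same transition law as the
#     Markov cohort model.

#' Discrete-event simulation configuration
#'
#' @param arrival_rates named events/year by diagnosis (any subset of
#'   ischemic, hemorrhagic, tia, mimic)
#' @param circadian a \code{circadian_profile}
#' @param service_time_hours MSU occupation time per accepted deployment
#' @param mode an \code{operating_mode}
#' @return an object of class \code{des_config}
#' @export
des_config <- function(arrival_rates, circadian = circadian_profile(),
                       service_time_hours = 1.5, mode = operating_mode(24, 7)) {
  stopifnot(all(arrival_rates >= 0), sum(arrival_rates) > 0,
            service_time_hours >= 0, inherits(mode, "operating_mode"),
            inherits(circadian, "circadian_profile"))
  structure(list(arrival_rates = arrival_rates, circadian = circadian,
                 service_time_hours = service_time_hours, mode = mode,
                 fleet_size = 1L),
            class = "des_config")
}

#' Simulate a time-stamped stroke call stream
#'
#' Nonhomogeneous Poisson arrivals by thinning: a homogeneous stream at the
#' peak hourly intensity is thinned by the ratio of the hour-of-day weight to
#' the peak weight (exact for the piecewise-constant circadian intensity).
#' Diagnoses are sampled in proportion to their rates; each event carries an
#' independent dispatcher-identification flag.
#'
#' @param config a \code{des_config}
#' @param years stream duration in years (365-day years)
#' @param seed integer seed
#' @param dispatcher_miss probability that a call is not identified at
#'   dispatch
#' @return an object of classes \code{msu_event_stream} and
#'   \code{data.frame}: columns \code{time_days} (continuous, sorted),
#'   \code{hour}, \code{diagnosis}, \code{dispatcher_identified}
#' @export
simulate_calls <- function(config, years, seed = 1, dispatcher_miss = 0) {
  stopifnot(inherits(config, "des_config"), years > 0)
  set.seed(seed)
  w <- config$circadian$weights
  daily_rate <- sum(config$arrival_rates) / 365
  lambda_max <- daily_rate * max(w)           # events per hour at the peak hour
  horizon_h <- years * 365 * 24

  n_cand <- stats::rpois(1, lambda_max * horizon_h)
  t_h <- sort(stats::runif(n_cand, 0, horizon_h))
  hour <- floor(t_h %% 24)
  keep <- stats::runif(n_cand) < w[hour + 1] / max(w)
  t_h <- t_h[keep]; hour <- hour[keep]
  n <- length(t_h)

  diag_p <- config$arrival_rates / sum(config$arrival_rates)
  out <- data.frame(
    time_days = t_h / 24,
    hour = hour,
    diagnosis = sample(names(diag_p), n, replace = TRUE, prob = diag_p),
    dispatcher_identified = stats::runif(n) >= dispatcher_miss,
    stringsAsFactors = FALSE)
  structure(out, class = c("msu_event_stream", "data.frame"),
            years = years, seed = seed, config = config)
}

# a 0-based day index is operational iff it falls on a scheduled weekday and
# within the first `operational_days` scheduled days of its 365-day year
.is_operational <- function(day_index, mode) {
  dow_ok <- (day_index %% 7) < mode$days_per_week
  day_of_year <- day_index %% 365
  # count scheduled days before this one in the year (full weeks + remainder)
  sched_before <- (day_of_year %/% 7) * mode$days_per_week +
    pmin(day_of_year %% 7, mode$days_per_week)
  dow_ok & (sched_before < mode$operational_days)
}

.in_window <- function(hour, mode) {
  s <- mode$window_start; h <- mode$hours_per_day
  if (h >= 24) return(rep(TRUE, length(hour)))
  e <- (s + h) %% 24
  if (s < e) hour >= s & hour < e else hour >= s | hour < e
}

#' Empirical case cascade from a simulated call stream
#'
#' Replays the stream against the service model: an event is managed iff it
#' falls inside the daily service window on an operational day, was
#' identified at dispatch, and the single MSU is not busy (busy means within
#' the service time of accepting a previous call).  Blocked-by-busy events
#' are the discrete-event counterpart of the analytic simultaneous-event
#' miss.
#'
#' @param stream an \code{msu_event_stream}
#' @param config a \code{des_config} (defaults to the stream's)
#' @return list of empirical annual stage counts, the per-event management
#'   flags, and the blocked fraction among otherwise-eligible events
#' @export
des_coverage <- function(stream, config = attr(stream, "config")) {
  stopifnot(inherits(stream, "msu_event_stream"))
  mode <- config$mode
  n <- nrow(stream)
  day_idx <- floor(stream$time_days)
  eligible <- .in_window(stream$hour, mode) &
    .is_operational(day_idx, mode) & stream$dispatcher_identified

  service_days <- config$service_time_hours / 24
  managed <- logical(n)
  busy_until <- -Inf
  tt <- stream$time_days
  for (i in seq_len(n)) {
    if (!eligible[i]) next
    if (tt[i] >= busy_until) {
      managed[i] <- TRUE
      busy_until <- tt[i] + service_days
    }
  }
  yrs <- attr(stream, "years")
  tab <- function(f) {
    counts <- table(factor(stream$diagnosis[f], levels = names(config$arrival_rates)))
    as.numeric(counts) / yrs
  }
  stages <- rbind(total = tab(rep(TRUE, n)),
                  in_window_operational = tab(.in_window(stream$hour, mode) &
                                                .is_operational(day_idx, mode)),
                  dispatcher_identified = tab(eligible),
                  managed = tab(managed))
  colnames(stages) <- names(config$arrival_rates)
  n_elig <- sum(eligible)
  list(stages = stages,
       managed_flags = managed,
       eligible_flags = eligible,
       blocked_fraction = if (n_elig) 1 - sum(managed) / n_elig else NA_real_,
       events = n)
}

#' Single-server Erlang loss probability
#'
#' Blocking probability of an M/G/1/1 loss system with offered load
#' \code{a = lambda * s}: \code{a / (1 + a)} (insensitive to the service-time
#' distribution).
#'
#' @param arrival_rate events per unit time
#' @param service_time mean occupation per event, same time unit
#' @return blocking probability
#' @export
erlang_b1 <- function(arrival_rate, service_time) {
  a <- arrival_rate * service_time
  a / (1 + a)
}

#' Patient-level microsimulation of the cohort model
#'
#' Simulates \code{n} independent patient trajectories under exactly the
#' process the cohort model takes expectations over: a 90-day entry state,
#' then per cycle death first, recurrence among survivors with redistribution
#' to same-or-worse states, accruing discounted utilities, long-term costs
#' and recurrent acute costs.  Agreement of the means with
#' \code{\link{run_cohort}} within Monte Carlo error validates the cohort
#' implementation.
#'
#' @param spec a \code{markov_spec}
#' @param params an \code{msu_params} object
#' @param n number of simulated patients
#' @param seed integer seed
#' @param perspective \code{"healthcare"} or \code{"societal"}
#' @param entry optional length-7 entry distribution override
#' @return list with mean discounted \code{cost} and \code{qalys}, their
#'   standard errors, and \code{n}
#' @export
microsimulate <- function(spec, params, n = 10000, seed = 1,
                          perspective = c("healthcare", "societal"),
                          entry = NULL) {
  perspective <- match.arg(perspective)
  stopifnot(inherits(spec, "markov_spec"), n >= 1)
  set.seed(seed)
  if (is.null(entry)) entry <- spec$redistribution
  disc <- (1 + spec$discount_rate)^-(seq_len(spec$horizon))
  u <- c(spec$utilities, 0)
  lt <- c(longterm_annual_cost(params, 0:5, perspective), 0)
  acute_recur <- c(param_value(params, "acute_cost_by_mrs"))
  dest <- lapply(0:5, function(k) .recur_dest(spec, k))

  state <- sample.int(7, n, replace = TRUE, prob = entry)   # 1..7, 7 = death
  cost <- acute_care_cost(params, 0:6, spec$strategy)[state]
  qaly <- numeric(n)
  for (t in seq_len(spec$horizon)) {
    r <- spec$recurrence[t]
    state0 <- state                     # snapshot: one transition per cycle
    for (k in 0:5) {
      idx <- which(state0 == k + 1)
      if (!length(idx)) next
      m <- spec$mortality[k + 1]
      dies <- stats::runif(length(idx)) < m
      state[idx[dies]] <- 7L
      surv <- idx[!dies]
      if (length(surv)) {
        recur <- stats::runif(length(surv)) < r
        ri <- surv[recur]
        if (length(ri)) {
          new_state <- sample.int(7, length(ri), replace = TRUE, prob = dest[[k + 1]])
          cost[ri] <- cost[ri] + acute_recur[new_state] * disc[t]
          state[ri] <- new_state
        }
      }
    }
    alive <- state < 7L
    qaly[alive] <- qaly[alive] + u[state[alive]] * disc[t]
    cost[alive] <- cost[alive] + lt[state[alive]] * disc[t]
  }
  list(cost = mean(cost), qalys = mean(qaly),
       se_cost = stats::sd(cost) / sqrt(n), se_qalys = stats::sd(qaly) / sqrt(n),
       n = n, strategy = spec$strategy, perspective = perspective)
}
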