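# Case-volume model: catchment population + incidence + miss cascade +
# service schedule -> annual patient counts managed by the MSU.

#' Define an MSU operating mode
#'
#' A service schedule: daily operating hours, days per week and the start of
#' the daily window.  Operational days per year are the scheduled days
#' (52.18 weeks times days per week) capped at 365 and at the annual maximum
#' (300 days by default, reflecting real-world downtime for maintenance and
#' staffing gaps).  Under that cap 6-day and 7-day schedules coincide.
#'
#' @param hours_per_day one of 8, 12, 16, 24
#' @param days_per_week one of 5, 6, 7
#' @param window_start hour of day (0-23) at which the daily window opens;
#'   windows may wrap past midnight
#' @param max_operational_days annual cap on operational days
#' @return an object of class \code{operating_mode}
#' @examples
#' operating_mode(8, 7)
#' operating_mode(16, 5, window_start = 6)
#' @export
operating_mode <- function(hours_per_day, days_per_week, window_start = 7,
                           max_operational_days = 300) {
  if (!hours_per_day %in% c(8, 12, 16, 24))
    stop("hours_per_day must be one of 8, 12, 16, 24")
  if (!days_per_week %in% c(5, 6, 7))
    stop("days_per_week must be one of 5, 6, 7")
  stopifnot(window_start >= 0, window_start < 24,
            max_operational_days > 0, max_operational_days <= 365)
  operational_days <- min(365, 52.18 * days_per_week, max_operational_days)
  structure(list(hours_per_day = hours_per_day,
                 days_per_week = days_per_week,
                 window_start = window_start,
                 operational_days = operational_days),
            class = "operating_mode")
}

#' @export
print.operating_mode <- function(x, ...) {
  cat(sprintf("MSU operating mode %dx%d: %d h/day from %02d:00, %d d/week, %.1f operational days/year\n",
              x$hours_per_day, x$days_per_week, x$hours_per_day,
              x$window_start, x$days_per_week, x$operational_days))
  invisible(x)
}

#' Mode label of the form "8x7"
#' @param mode an \code{operating_mode}
#' @return character label
#' @export
mode_label <- function(mode) sprintf("%dx%d", mode$hours_per_day, mode$days_per_week)

#' Parse a mode label such as "16x7"
#' @param label character label \code{"<hours>x<days>"}
#' @param ... passed to \code{operating_mode}
#' @return an \code{operating_mode}
#' @export
parse_mode <- function(label, ...) {
  parts <- strsplit(label, "x", fixed = TRUE)[[1]]
  if (length(parts) != 2 || anyNA(suppressWarnings(as.numeric(parts))))
    stop("invalid mode label '", label, "'; expected e.g. \"8x7\", \"16x5\"")
  operating_mode(as.numeric(parts[1]), as.numeric(parts[2]), ...)
}

#' Circadian profile of stroke onsets
#'
#' 24 nonnegative hour-of-day weights summing to 1.
#'
#' @param weights numeric vector of length 24; defaults to the shipped
#'   morning-peaked profile
#' @return an object of class \code{circadian_profile}
#' @export
circadian_profile <- function(weights = param_value(msu_parameters(), "circadian_weights")) {
  weights <- as.numeric(weights)
  if (length(weights) != 24) stop("circadian profile needs 24 hourly weights")
  if (any(weights < 0)) stop("circadian weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) stop("circadian weights must sum to 1")
  structure(list(weights = weights), class = "circadian_profile")
}

#' Uniform circadian profile
#' @return a \code{circadian_profile} with equal hourly weights
#' @export
uniform_circadian <- function() circadian_profile(rep(1 / 24, 24))

# hours of day (0-23) covered by the daily window, wrap-around allowed
.window_hours <- function(mode) {
  (mode$window_start + seq_len(mode$hours_per_day) - 1) %% 24
}

#' Fraction of annual stroke onsets inside the service window
#'
#' The product of the operational-day fraction (operational days / 365) and
#' the circadian mass falling inside the daily service window.  Nondecreasing
#' in hours per day and days per week.
#'
#' @param mode an \code{operating_mode}
#' @param circadian a \code{circadian_profile}
#' @return a fraction in \code{[0, 1]}
#' @examples
#' window_coverage(operating_mode(24, 7), uniform_circadian())  # 300/365
#' @export
window_coverage <- function(mode, circadian = circadian_profile()) {
  stopifnot(inherits(mode, "operating_mode"), inherits(circadian, "circadian_profile"))
  day_frac <- mode$operational_days / 365
  hour_mass <- sum(circadian$weights[.window_hours(mode) + 1])
  day_frac * hour_mass
}

#' Annual case counts by diagnosis
#'
#' @param population catchment population (persons)
#' @param incidence named per-100,000/year rates for ischemic, hemorrhagic,
#'   tia and mimic presentations
#' @return named numeric vector of expected annual cases
#' @export
annual_cases <- function(population,
                         incidence = param_value(msu_parameters(), "incidence_per_100k")) {
  stopifnot(population >= 0, all(incidence >= 0))
  population * incidence / 1e5
}

#' Logistic miss fraction
#'
#' Misses from logistic problems: a base fraction plus a slope per 100,000
#' inhabitants covered (simultaneous stroke events), capped at 1.
#'
#' @param population catchment population
#' @param base intercept fraction (default 0.08)
#' @param slope added fraction per 100,000 inhabitants (default 0.025)
#' @return miss fraction in \code{[0, 1]}, monotone nondecreasing in population
#' @examples
#' logistic_miss(750000)   # 0.08 + 0.025 * 7.5 = 0.2675
#' @export
logistic_miss <- function(population, base = 0.08, slope = 0.025) {
  stopifnot(population >= 0, base >= 0, slope >= 0)
  pmin(base + slope * population / 1e5, 1)
}

#' Combined miss fraction among in-window, dispatch-eligible cases
#'
#' Two combination rules for the dispatcher miss and the logistic miss are
#' available.  \code{"additive"} treats them as mutually exclusive causes,
#' \code{missed = dispatcher + base + slope * population / 100,000} (capped at
#' 1); this reproduces the reference catchment-size table of missed-case
#' percentages.  \code{"multiplicative"} treats them as independent,
#' \code{missed = 1 - (1 - dispatcher) (1 - logistic)}.
#'
#' @param population catchment population
#' @param dispatcher_miss dispatch misidentification fraction
#' @param base,slope logistic-miss rule parameters
#' @param model \code{"additive"} (default) or \code{"multiplicative"}
#' @return total miss fraction in \code{[0, 1]}
#' @export
miss_fraction <- function(population, dispatcher_miss = 0.37,
                          base = 0.08, slope = 0.025,
                          model = c("additive", "multiplicative")) {
  model <- match.arg(model)
  lm_ <- logistic_miss(population, base, slope)
  if (model == "additive") pmin(dispatcher_miss + base + slope * population / 1e5, 1)
  else 1 - (1 - dispatcher_miss) * (1 - lm_)
}

#' Build the annual case cascade
#'
#' The attrition funnel from incident cases in the catchment to patients
#' managed by the MSU, per diagnosis: total cases, EMS-contacted, MSU-criteria
#' met, inside the service window, dispatcher-identified, and not missed for
#' logistic reasons (= managed).  Counts are real-valued expectations; no
#' rounding before reporting.
#'
#' @param params an \code{msu_params} object
#' @param mode an \code{operating_mode}
#' @param population catchment population; defaults to the parameter set's
#'   \code{base_population}
#' @param circadian a \code{circadian_profile}; defaults to the parameter
#'   set's weights
#' @param miss_model \code{"additive"} or \code{"multiplicative"}, see
#'   \code{\link{miss_fraction}}
#' @param coverage_denominator \code{"total"} (managed IS / incident IS,
#'   default) or \code{"eligible"} (managed IS / dispatch-eligible IS)
#' @return an object of class \code{case_cascade}: a stage-by-diagnosis
#'   matrix plus the ischemic-stroke coverage fraction
#' @examples
#' cc <- build_cascade(msu_parameters(), operating_mode(8, 7))
#' cc$managed["ischemic"]
#' @export
build_cascade <- function(params, mode, population = NULL, circadian = NULL,
                          miss_model = c("additive", "multiplicative"),
                          coverage_denominator = c("total", "eligible")) {
  stopifnot(inherits(params, "msu_params"), inherits(mode, "operating_mode"))
  miss_model <- match.arg(miss_model)
  coverage_denominator <- match.arg(coverage_denominator)
  if (is.null(population)) population <- param_value(params, "base_population")
  if (is.null(circadian))
    circadian <- circadian_profile(param_value(params, "circadian_weights"))

  total <- annual_cases(population, param_value(params, "incidence_per_100k"))
  ems   <- total * param_value(params, "ems_contact_rate")
  crit  <- ems * param_value(params, "msu_criteria_rate")
  wc    <- window_coverage(mode, circadian)
  inwin <- crit * wc

  d  <- param_value(params, "dispatcher_miss")
  lb <- param_value(params, "logistic_miss_base")
  ls <- param_value(params, "logistic_miss_slope")
  disp <- inwin * (1 - d)
  if (miss_model == "additive") {
    total_miss <- miss_fraction(population, d, lb, ls, model = "additive")
    managed <- inwin * (1 - total_miss)
  } else {
    managed <- disp * (1 - logistic_miss(population, lb, ls))
  }
  managed <- pmax(managed, 0)

  stages <- rbind(total_cases = total, ems_contacted = ems,
                  criteria_met = crit, in_service_window = inwin,
                  dispatcher_identified = disp, managed = managed)
  denom <- switch(coverage_denominator,
                  total = total["ischemic"],
                  eligible = crit["ischemic"])
  structure(list(stages = stages,
                 managed = managed,
                 managed_total = sum(managed),
                 coverage_fraction = unname(managed["ischemic"] / denom),
                 window_coverage = wc,
                 miss_model = miss_model,
                 population = population,
                 mode = mode),
            class = "case_cascade")
}

#' @export
print.case_cascade <- function(x, digits = 1, ...) {
  cat(sprintf("MSU case cascade (%s, population %s, %s miss model)\n",
              mode_label(x$mode), format(x$population, big.mark = ","),
              x$miss_model))
  print(round(x$stages, digits))
  cat(sprintf("IS coverage fraction: %.3f; managed patients/year: %.1f\n",
              x$coverage_fraction, x$managed_total))
  invisible(x)
}

#' Cascade as a tidy data frame
#' @param x a \code{case_cascade}
#' @param ... unused
#' @return data.frame with columns diagnosis, stage, count
#' @export
as.data.frame.case_cascade <- function(x, ...) {
  st <- x$stages
  data.frame(diagnosis = rep(colnames(st), each = nrow(st)),
             stage = rep(rownames(st), times = ncol(st)),
             count = as.vector(st),
             stringsAsFactors = FALSE)
}
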