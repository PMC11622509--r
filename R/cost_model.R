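# MSU programme cost model: annualized investment, running and staffing
# costs; per-patient deployment costs; acute and long-term patient costs
# by mRS level and perspective.  All money in 2021 euros.

#' Annual MSU programme cost
#'
#' Investment is straight-line depreciation of the capital items over the
#' configured timeframe; running costs are mode-independent; staffing scales
#' with staffed hours (hours per day times operational days) for the on-board
#' roles, with fixed annual allocations for the remote radiologist and the
#' fractional project manager, plus training, all multiplied by the
#' administration overhead.  With teleneurology the on-board neurologist's
#' hours are replaced by remote-assessment hours.
#'
#' @param params an \code{msu_params} object
#' @param mode an \code{operating_mode}
#' @param teleneurology logical; replace the on-board neurologist with remote
#'   teleneurological assessment
#' @return list with components \code{investment}, \code{running},
#'   \code{staffing}, \code{total} (euros/year) and \code{shares} (fractions
#'   summing to 1)
#' @examples
#' annual_program_cost(msu_parameters(), operating_mode(8, 7))
#' @export
annual_program_cost <- function(params, mode, teleneurology = FALSE) {
  stopifnot(inherits(params, "msu_params"), inherits(mode, "operating_mode"))
  pv <- function(n) param_value(params, n)

  capital <- pv("capital_vehicle") + pv("capital_ct") + pv("capital_equipment")
  investment <- capital / pv("depreciation_years")
  running <- pv("running_annual")

  staffed_hours <- mode$hours_per_day * mode$operational_days
  physician_rate <- if (teleneurology) pv("remote_neurologist_hourly")
                    else pv("neurologist_hourly")
  hourly_rate <- pv("paramedic_hourly") + physician_rate + pv("radiology_tech_hourly")
  fixed_staff <- pv("remote_radiologist_annual") +
    pv("project_manager_annual") * pv("project_manager_fte") +
    pv("training_annual")
  staffing <- (hourly_rate * staffed_hours + fixed_staff) * (1 + pv("overhead"))

  total <- investment + running + staffing
  shares <- c(investment = investment, running = running, staffing = staffing) / total
  list(investment = investment, running = running, staffing = staffing,
       total = total, shares = shares, teleneurology = teleneurology)
}

#' Per-patient MSU deployment cost
#'
#' The annual programme cost divided by the managed count for the chosen
#' denominator, plus any variable cost per deployment.  Strictly decreasing
#' in the managed count.
#'
#' @param annual_cost annual programme cost in euros (a number or the list
#'   returned by \code{annual_program_cost})
#' @param cascade a \code{case_cascade}
#' @param denominator \code{"is"} (ischemic stroke patients only) or
#'   \code{"all"} (all managed patients)
#' @param variable_cost euros added per deployment (rendezvous consumables
#'   etc.); default 0
#' @return euros per patient
#' @export
per_patient_deployment_cost <- function(annual_cost, cascade,
                                        denominator = c("is", "all"),
                                        variable_cost = 0) {
  denominator <- match.arg(denominator)
  if (is.list(annual_cost)) annual_cost <- annual_cost$total
  stopifnot(inherits(cascade, "case_cascade"), annual_cost >= 0, variable_cost >= 0)
  n <- switch(denominator, is = unname(cascade$managed["ischemic"]),
              all = cascade$managed_total)
  if (n <= 0) stop("managed patient count is zero; per-patient cost undefined")
  annual_cost / n + variable_cost
}

#' Acute-care cost of an ischemic stroke admission
#'
#' The direct hospital cost by 90-day mRS level, plus strategy-specific
#' short-term components: the conventional arm adds EMS transport and the
#' expected cost of secondary interhospital transfers; the MSU arm adds the
#' rendezvous-system EMS transport and never a secondary transfer (obviated
#' by pre-hospital imaging and triage).
#'
#' @param params an \code{msu_params} object
#' @param mrs integer 0-5, or 6 for death before 90 days
#' @param strategy \code{"conventional"} or \code{"msu"}
#' @return euros
#' @export
acute_care_cost <- function(params, mrs, strategy = c("conventional", "msu")) {
  strategy <- match.arg(strategy)
  if (any(!mrs %in% 0:6)) stop("mRS level must be an integer in 0..6")
  base <- param_value(params, "acute_cost_by_mrs")[mrs + 1]
  extra <- if (strategy == "conventional") {
    param_value(params, "conventional_transport_cost") +
      param_value(params, "secondary_transfer_prob") *
      param_value(params, "secondary_transfer_cost")
  } else {
    param_value(params, "msu_transport_cost")
  }
  unname(base + extra)
}

#' Long-term annual post-stroke cost
#'
#' Healthcare perspective: stroke-induced additional hospitalization days per
#' year.  Societal perspective adds insurance-covered nursing, family-covered
#' nursing, and productivity losses under the human capital approach (gross
#' wage times employment rate times lost ability to work), the latter only
#' below the retirement-age cutoff.
#'
#' @param params an \code{msu_params} object
#' @param mrs integer 0-5
#' @param perspective \code{"healthcare"} or \code{"societal"}
#' @param age patient age in years during the cycle; defaults to the cohort
#'   mean age
#' @return euros per year
#' @export
longterm_annual_cost <- function(params, mrs,
                                 perspective = c("healthcare", "societal"),
                                 age = param_value(params, "mean_age")) {
  perspective <- match.arg(perspective)
  if (any(!mrs %in% 0:5)) stop("mRS level must be an integer in 0..5")
  hc <- param_value(params, "lt_hc_annual_by_mrs")[mrs + 1]
  if (perspective == "healthcare") return(unname(hc))
  nursing <- param_value(params, "lt_nursing_insurance_by_mrs")[mrs + 1] +
    param_value(params, "lt_nursing_family_by_mrs")[mrs + 1]
  productivity <- if (age < param_value(params, "retirement_age")) {
    param_value(params, "gross_annual_wage") *
      param_value(params, "employment_rate") *
      (1 - param_value(params, "ability_to_work_by_mrs")[mrs + 1])
  } else rep(0, length(mrs))
  unname(hc + nursing + productivity)
}
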