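# Front end: one call runs the whole pipeline (cascade -> programme costs ->
# Markov cohort -> incremental synthesis) and returns a classed result.

#' Cost-effectiveness analysis of a mobile stroke unit service
#'
#' Runs the full decision model for one service configuration: the annual
#' case cascade for the catchment, the programme cost model for the operating
#' mode, the 5-year Markov cohort model of post-stroke outcomes under
#' conventional versus MSU-based care, and the incremental synthesis (ICER
#' and net monetary benefit) per perspective.
#'
#' @param params an \code{msu_params} object (defaults to the shipped base
#'   case)
#' @param mode an \code{operating_mode} or a label such as \code{"8x7"}
#' @param population catchment population; defaults to the parameter set's
#'   \code{base_population}
#' @param perspectives character vector out of \code{"healthcare"},
#'   \code{"societal"}
#' @param teleneurology logical, see \code{\link{annual_program_cost}}
#' @param half_cycle logical, see \code{\link{run_cohort}}
#' @param miss_model \code{"additive"} or \code{"multiplicative"}, see
#'   \code{\link{miss_fraction}}
#' @return an object of class \code{msu_cea} holding the cascade, programme
#'   cost breakdown, per-patient deployment costs, per-perspective strategy
#'   outcomes and \code{cea_result}s
#' @examples
#' fit <- msu_cea()
#' fit
#' summary(fit)
#' @export
msu_cea <- function(params = msu_parameters(), mode = operating_mode(8, 7),
                    population = NULL,
                    perspectives = c("healthcare", "societal"),
                    teleneurology = FALSE, half_cycle = FALSE,
                    miss_model = c("additive", "multiplicative")) {
  if (is.character(mode)) mode <- parse_mode(mode)
  miss_model <- match.arg(miss_model)
  perspectives <- match.arg(perspectives, several.ok = TRUE)
  if (is.null(population)) population <- param_value(params, "base_population")

  cascade <- build_cascade(params, mode, population, miss_model = miss_model)
  program <- annual_program_cost(params, mode, teleneurology)
  deploy_is <- per_patient_deployment_cost(program, cascade, "is",
                                           param_value(params, "deployment_variable_cost"))
  deploy_all <- per_patient_deployment_cost(program, cascade, "all",
                                            param_value(params, "deployment_variable_cost"))
  wtp <- param_value(params, "wtp")

  outcomes <- list(); cea <- list()
  for (p in perspectives) {
    cmp <- compare_strategies(params, cascade, program, p, half_cycle)
    outcomes[[p]] <- cmp
    cea[[p]] <- icer(cmp$conventional, cmp$msu, wtp = wtp, perspective = p)
  }
  structure(list(params = params, mode = mode, population = population,
                 cascade = cascade, program = program,
                 deployment_cost = c(per_is = deploy_is, per_managed = deploy_all),
                 outcomes = outcomes, cea = cea, wtp = wtp,
                 teleneurology = teleneurology, half_cycle = half_cycle,
                 call = match.call()),
            class = "msu_cea")
}

#' @export
print.msu_cea <- function(x, ...) {
  cat(sprintf("MSU cost-effectiveness analysis: mode %s, population %s\n",
              mode_label(x$mode), format(x$population, big.mark = ",")))
  cat(sprintf("  managed IS patients/year: %.1f (all diagnoses: %.1f)\n",
              x$cascade$managed["ischemic"], x$cascade$managed_total))
  cat(sprintf("  deployment cost: EUR %s per IS patient, EUR %s per managed patient\n",
              format(round(x$deployment_cost["per_is"]), big.mark = ","),
              format(round(x$deployment_cost["per_managed"]), big.mark = ",")))
  for (p in names(x$cea)) print(x$cea[[p]])
  invisible(x)
}

#' @export
summary.msu_cea <- function(object, ...) {
  structure(list(fit = object), class = "summary.msu_cea")
}

#' @export
print.summary.msu_cea <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nAnnual programme cost (EUR/year):\n")
  pc <- f$program
  for (nm in c("investment", "running", "staffing"))
    cat(sprintf("  %-10s %12s  (%.1f%%)\n", nm,
                format(round(pc[[nm]]), big.mark = ","), 100 * pc$shares[[nm]]))
  cat(sprintf("  %-10s %12s\n", "total", format(round(pc$total), big.mark = ",")))
  cat("\nCase cascade (expected patients/year):\n")
  print(round(f$cascade$stages, 1))
  cat("\nPer dispatched patient (discounted, 5-year horizon):\n")
  for (p in names(f$outcomes)) {
    o <- f$outcomes[[p]]
    cat(sprintf("  %s: conventional EUR %s / %.3f QALYs; MSU EUR %s / %.3f QALYs\n",
                p, format(round(o$conventional$cost), big.mark = ","),
                o$conventional$qalys,
                format(round(o$msu$cost), big.mark = ","), o$msu$qalys))
  }
  invisible(x)
}

#' Cost share and cascade display
#'
#' Bar display of the annual programme cost composition and of the case
#' funnel for ischemic stroke.
#'
#' @param x an \code{msu_cea} object
#' @param ... passed to \code{barplot}
#' @export
plot.msu_cea <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(100 * unlist(x$program$shares),
                    ylab = "share of annual cost (%)",
                    main = "Programme cost composition", las = 2, ...)
  graphics::barplot(x$cascade$stages[, "ischemic"],
                    ylab = "patients/year",
                    main = "Ischemic stroke case funnel", las = 2, ...)
  invisible(x)
}

#' Probabilistic draws from a fitted analysis
#'
#' \code{simulate} on an \code{msu_cea} object re-samples all parameters with
#' an attached distribution and re-runs the pipeline per draw — the
#' probabilistic sensitivity analysis — returning the incremental cost/effect
#' cloud (see \code{\link{run_psa}}).
#'
#' @param object an \code{msu_cea} object
#' @param nsim number of Monte Carlo iterations
#' @param seed integer seed
#' @param ... passed to \code{run_psa}
#' @return an \code{msu_psa} object
#' @export
simulate.msu_cea <- function(object, nsim = 1000, seed = 1, ...) {
  run_psa(object$params, n = nsim, seed = seed, mode = object$mode,
          population = object$population, ...)
}
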