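# Scenario grids over operating modes and catchment populations, two-way
# deterministic sensitivity analysis, and probabilistic sensitivity analysis
# with cost-effectiveness plane and acceptability curves.

#' Default operating-mode set
#'
#' The 12 combinations of 8/12/16/24 hours per day with 5/6/7 days per week.
#' Under the 300-day annual cap the 6-day and 7-day schedules coincide.
#'
#' @param window_start daily window start hour
#' @return list of \code{operating_mode} objects named by label
#' @export
default_mode_set <- function(window_start = 7) {
  grid <- expand.grid(hours = c(8, 12, 16, 24), days = c(5, 6, 7))
  modes <- mapply(function(h, d) operating_mode(h, d, window_start),
                  grid$hours, grid$days, SIMPLIFY = FALSE)
  stats::setNames(modes, vapply(modes, mode_label, ""))
}

#' Scenario grid over operating modes and catchment populations
#'
#' One full pipeline evaluation (cascade, programme cost, Markov cohort,
#' incremental synthesis) per mode-population cell; deterministic given the
#' parameter set.
#'
#' @param params an \code{msu_params} object
#' @param modes list of \code{operating_mode}s (or character labels)
#' @param populations numeric vector of catchment populations
#' @param ... passed to \code{msu_cea}
#' @return an object of classes \code{msu_scenario_grid} and
#'   \code{data.frame}: one row per cell with coverage fraction, missed IS
#'   fraction, managed IS/year, deployment cost per IS patient, and ICERs for
#'   both perspectives; cells with zero managed patients are flagged in
#'   \code{degenerate}, not fatal.
#' @examples
#' g <- scenario_grid(msu_parameters(), list("8x7", "16x7"), c(500000, 750000))
#' @export
scenario_grid <- function(params, modes = default_mode_set(),
                          populations = param_value(params, "base_population"),
                          ...) {
  if (!length(modes)) stop("empty mode list")
  if (!length(populations)) stop("empty population list")
  modes <- lapply(modes, function(m) if (is.character(m)) parse_mode(m) else m)
  rows <- list()
  for (m in modes) for (pop in populations) {
    cc <- build_cascade(params, m, pop)
    degenerate <- cc$managed_total <= 0 || cc$managed["ischemic"] <= 0
    if (degenerate) {
      rows[[length(rows) + 1]] <- data.frame(
        mode = mode_label(m), population = pop, coverage = cc$coverage_fraction,
        missed_is_fraction = NA_real_, managed_is = 0, deployment_cost_is = NA_real_,
        icer_healthcare = NA_real_, icer_societal = NA_real_,
        nmb_healthcare = NA_real_, nmb_societal = NA_real_, degenerate = TRUE)
      next
    }
    fit <- msu_cea(params, m, pop, ...)
    rows[[length(rows) + 1]] <- data.frame(
      mode = mode_label(m), population = pop,
      coverage = cc$coverage_fraction,
      missed_is_fraction = miss_fraction(pop,
        param_value(params, "dispatcher_miss"),
        param_value(params, "logistic_miss_base"),
        param_value(params, "logistic_miss_slope")),
      managed_is = unname(cc$managed["ischemic"]),
      deployment_cost_is = unname(fit$deployment_cost["per_is"]),
      icer_healthcare = fit$cea$healthcare$icer,
      icer_societal = fit$cea$societal$icer,
      nmb_healthcare = fit$cea$healthcare$nmb,
      nmb_societal = fit$cea$societal$nmb,
      degenerate = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("msu_scenario_grid", "data.frame")
  out
}

#' @export
plot.msu_scenario_grid <- function(x, perspective = "healthcare", ...) {
  icer_col <- paste0("icer_", perspective)
  if (length(unique(x$population)) > 1) {
    graphics::plot(x$population, x[[icer_col]], type = "b", pch = 19,
                   xlab = "catchment population", ylab = "ICER (EUR/QALY)",
                   main = paste("ICER by catchment size,", perspective), ...)
  } else {
    graphics::plot(100 * x$coverage, x[[icer_col]], pch = 19,
                   xlab = "IS coverage (%)", ylab = "ICER (EUR/QALY)",
                   main = paste("Operating modes,", perspective), ...)
    graphics::text(100 * x$coverage, x[[icer_col]], x$mode, pos = 3, cex = 0.7)
  }
  invisible(x)
}

#' Two-way deterministic sensitivity analysis
#'
#' Varies the total missed-stroke fraction (replacing the dispatcher and
#' logistic misses) against the operating mode and reports the annual
#' programme-scale net monetary benefit per cell:
#' \code{WTP x managed_IS x dQALY_IS - (annual programme cost +
#' managed x incremental downstream cost per patient)}.  The programme scale
#' keeps the degenerate all-missed limit well defined (NMB equals minus the
#' programme cost).  NMB is nonincreasing in the missed fraction at fixed
#' mode.
#'
#' @param params an \code{msu_params} object
#' @param missed_fractions numeric vector in \code{[0, 1]}
#' @param modes list of \code{operating_mode}s or labels
#' @param wtp willingness-to-pay; defaults to the parameter set's threshold
#' @param population catchment population
#' @return data.frame with columns mode, missed_fraction, managed_is,
#'   nmb_annual (healthcare perspective)
#' @export
two_way_dsa <- function(params, missed_fractions = seq(0, 1, by = 0.1),
                        modes = default_mode_set(),
                        wtp = param_value(params, "wtp"),
                        population = param_value(params, "base_population")) {
  stopifnot(all(missed_fractions >= 0), all(missed_fractions <= 1))
  modes <- lapply(modes, function(m) if (is.character(m)) parse_mode(m) else m)

  # strategy deltas per IS patient are independent of the miss cascade
  is_conv <- run_cohort(markov_spec(params, "conventional"), params, "healthcare")
  is_msu <- run_cohort(markov_spec(params, "msu"), params, "healthcare")
  dq_is <- is_msu$qalys - is_conv$qalys
  dc_is <- is_msu$cost - is_conv$cost

  rows <- list()
  for (m in modes) {
    program <- annual_program_cost(params, m)
    cc0 <- build_cascade(params, m, population)   # managed before miss stage
    eligible <- cc0$stages["in_service_window", ]
    for (mf in missed_fractions) {
      managed <- eligible * (1 - mf)
      nmb_annual <- wtp * managed["ischemic"] * dq_is -
        (program$total + managed["ischemic"] * dc_is)
      rows[[length(rows) + 1]] <- data.frame(
        mode = mode_label(m), missed_fraction = mf,
        managed_is = unname(managed["ischemic"]),
        nmb_annual = unname(nmb_annual))
    }
  }
  do.call(rbind, rows)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo resampling of every parameter with an attached distribution;
#' each iteration re-runs the full deterministic pipeline (the cohort model
#' stays deterministic within an iteration) and records the incremental cost
#' and effect per dispatched patient for both perspectives.  The
#' cost-effectiveness acceptability curve reports, per willingness-to-pay
#' value, the fraction of iterations with nonnegative net monetary benefit.
#'
#' @param params an \code{msu_params} object
#' @param n number of iterations (base case 10,000)
#' @param seed integer seed for the whole run
#' @param wtp_grid thresholds for the acceptability curve (euros/QALY)
#' @param mode an \code{operating_mode} or label
#' @param population catchment population
#' @return an object of class \code{msu_psa}: \code{iterations} (data.frame
#'   of dC/dE per perspective), \code{ceac} (long data.frame over the WTP
#'   grid), \code{ce_fraction} at the parameter set's threshold, \code{seed}
#' @export
run_psa <- function(params, n = 1000, seed = 1,
                    wtp_grid = seq(0, 150000, by = 1000),
                    mode = operating_mode(8, 7),
                    population = param_value(params, "base_population")) {
  if (n <= 0) stop("n must be positive")
  if (is.character(mode)) mode <- parse_mode(mode)
  set.seed(seed)
  res <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("dc_healthcare", "de_healthcare",
                                        "dc_societal", "de_societal")))
  for (i in seq_len(n)) {
    ps <- sample_parameters(params)
    fit <- msu_cea(ps, mode, population)
    res[i, ] <- c(fit$cea$healthcare$delta_cost, fit$cea$healthcare$delta_qalys,
                  fit$cea$societal$delta_cost, fit$cea$societal$delta_qalys)
  }
  iterations <- as.data.frame(res)
  wtp0 <- param_value(params, "wtp")
  cf <- function(dc, de, w) mean(w * de - dc >= 0)
  ceac <- do.call(rbind, lapply(wtp_grid, function(w) data.frame(
    wtp = w,
    healthcare = cf(iterations$dc_healthcare, iterations$de_healthcare, w),
    societal = cf(iterations$dc_societal, iterations$de_societal, w))))
  structure(list(iterations = iterations, ceac = ceac,
                 ce_fraction = c(
                   healthcare = cf(iterations$dc_healthcare, iterations$de_healthcare, wtp0),
                   societal = cf(iterations$dc_societal, iterations$de_societal, wtp0)),
                 wtp = wtp0, n = n, seed = seed,
                 mode = mode, population = population),
            class = "msu_psa")
}

#' @export
print.msu_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations (seed %d), mode %s, population %s\n",
              x$n, x$seed, mode_label(x$mode), format(x$population, big.mark = ",")))
  cat(sprintf("  cost-effective at WTP EUR %s/QALY: %.1f%% (healthcare), %.1f%% (societal)\n",
              format(x$wtp, big.mark = ","),
              100 * x$ce_fraction["healthcare"], 100 * x$ce_fraction["societal"]))
  invisible(x)
}

#' Cost-effectiveness plane and acceptability curves
#'
#' @param x an \code{msu_psa} object
#' @param perspective \code{"healthcare"} or \code{"societal"} for the plane
#' @param ... unused
#' @export
plot.msu_psa <- function(x, perspective = c("healthcare", "societal"), ...) {
  perspective <- match.arg(perspective)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4.5, 4.5, 3, 1))
  on.exit(graphics::par(op))
  dc <- x$iterations[[paste0("dc_", perspective)]]
  de <- x$iterations[[paste0("de_", perspective)]]
  ce <- x$wtp * de - dc >= 0
  graphics::plot(de, dc, pch = ".", cex = 2,
                 col = ifelse(ce, "forestgreen", "firebrick"),
                 xlab = "incremental QALYs", ylab = "incremental cost (EUR)",
                 main = paste("CE plane,", perspective))
  graphics::abline(0, x$wtp, lty = 2); graphics::abline(h = 0, v = 0, col = "grey")
  graphics::plot(x$ceac$wtp, 100 * x$ceac[[perspective]], type = "l", lwd = 2,
                 ylim = c(0, 100), xlab = "willingness-to-pay (EUR/QALY)",
                 ylab = "probability cost-effective (%)",
                 main = "Acceptability curve")
  graphics::abline(v = x$wtp, lty = 2)
  invisible(x)
}
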