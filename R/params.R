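# Domains understood by the validator:
#   probability  - each element in [0, 1]
#   simplex      - nonnegative, sums to 1 (tolerance 1e-6)
#   cost         - nonnegative
#   count        - nonnegative
#   rate         - nonnegative
#   fraction     - each element in [0, 1]
#   real         - any finite value
.param_domains <- c("probability", "simplex", "cost", "count", "rate",
                    "fraction", "real")

.mrs_labels <- paste0("mRS", 0:5)
.diagnoses  <- c("ischemic", "hemorrhagic", "tia", "mimic")

# Full default registry.  Provenance "paper" marks values printed in the main
# text of the source cost-effectiveness study; "assumed" marks values standing
# in for its (unavailable) supplementary tables, chosen from German
# epidemiology and MSU programme literature and anchored to aggregates the
# main text does print.  PSA specs: beta (effective sample size n_eff),
# gamma (coefficient of variation cv), dirichlet (concentration conc),
# uniform (half-width fraction hw), lognormal (sdlog).
.default_registry <- function() {
  p <- function(value, domain, provenance, note, psa = NULL)
    list(value = value, domain = domain, provenance = provenance,
         note = note, psa = psa)
  beta_  <- function(n_eff = 100) list(family = "beta", n_eff = n_eff)
  gamma_ <- function(cv = 0.2)    list(family = "gamma", cv = cv)
  diri_  <- function(conc = 100)  list(family = "dirichlet", conc = conc)

  list(
    ## -- cohort and analysis constants (printed in the main text) ----------
    mean_age = p(72.5, "count", "paper", "average patient age, German MSU trials"),
    horizon_years = p(5, "count", "paper", "simulation horizon"),
    cycle_years = p(1, "count", "paper", "Markov cycle length"),
    discount_rate = p(0.03, "fraction", "paper", "annual discounting of costs and outcomes"),
    base_population = p(750000, "count", "paper", "base-case catchment population"),
    dispatcher_miss = p(0.37, "probability", "paper",
                        "stroke misidentification at dispatch", beta_(150)),
    logistic_miss_base = p(0.08, "probability", "paper",
                           "misses from logistic problems, intercept", beta_(150)),
    logistic_miss_slope = p(0.025, "fraction", "paper",
                            "additional miss fraction per 100,000 inhabitants (simultaneous events)"),
    ivt_rate_msu = p(0.121, "probability", "paper",
                     "IVT treatment rate under MSU care", beta_(200)),
    overhead = p(0.22, "fraction", "paper", "hospital administration overhead on staffing"),
    depreciation_years = p(6, "count", "paper", "straight-line hardware depreciation"),
    max_operational_days = p(300, "count", "paper", "maximum operational days per year"),
    wtp = p(47901, "cost", "paper", "willingness-to-pay per QALY (1x German GDP per capita)"),
    psa_iterations = p(10000, "count", "paper", "Monte Carlo iterations for PSA"),

    ## -- case volume --------------------------------------------------------
    incidence_per_100k = p(
      stats::setNames(c(200, 35, 115, 205), .diagnoses), "rate", "assumed",
      "annual incidence of MSU-relevant presentations per 100,000 (German rates; mimic rate from MSU dispatch reports)",
      gamma_(0.10)),
    ems_contact_rate = p(0.75, "probability", "assumed",
                         "fraction of cases contacting emergency services in time",
                         beta_(100)),
    msu_criteria_rate = p(0.7156, "probability", "assumed",
                          "fraction of EMS-contacted cases fulfilling MSU alarming criteria (anchored to 124 managed IS/year in the base case)",
                          beta_(100)),
    circadian_weights = p(
      c(0.016, 0.013, 0.011, 0.011, 0.013, 0.022,
        0.049, 0.060, 0.071, 0.077, 0.074, 0.068,
        0.060, 0.055, 0.052, 0.050, 0.048, 0.046,
        0.044, 0.042, 0.038, 0.033, 0.027, 0.020),
      "simplex", "assumed",
      "hour-of-day fractions of stroke onsets (morning-peaked circadian pattern)"),
    window_start_hour = p(7, "count", "assumed", "daily service window start (hour of day)"),

    ## -- programme costs (2021 EUR) -----------------------------------------
    capital_vehicle = p(500000, "cost", "assumed", "MSU vehicle", gamma_(0.15)),
    capital_ct = p(420000, "cost", "assumed", "on-board CT scanner", gamma_(0.15)),
    capital_equipment = p(260000, "cost", "assumed",
                          "point-of-care lab, telemedicine and other equipment", gamma_(0.15)),
    running_annual = p(468000, "cost", "assumed",
                       "annual running costs (maintenance, fuel, consumables, telecommunication)",
                       gamma_(0.15)),
    paramedic_hourly = p(36, "cost", "assumed", "paramedic cost per staffed hour", gamma_(0.10)),
    neurologist_hourly = p(83, "cost", "assumed", "on-board neurologist cost per staffed hour", gamma_(0.10)),
    radiology_tech_hourly = p(42, "cost", "assumed", "radiology technician cost per staffed hour", gamma_(0.10)),
    remote_neurologist_hourly = p(35.8, "cost", "assumed",
                                  "remote teleneurology assessment cost per staffed hour", gamma_(0.10)),
    remote_radiologist_annual = p(30000, "cost", "assumed",
                                  "remote radiologist, fractional allocation (not exclusive to MSU)"),
    project_manager_annual = p(120000, "cost", "assumed", "physician project manager, full-time cost"),
    project_manager_fte = p(0.5, "fraction", "paper", "project manager allocation to MSU"),
    training_annual = p(0, "cost", "assumed",
                        "additional training costs as a fixed staffing add-on (0 = included in role rates)"),
    deployment_variable_cost = p(0, "cost", "assumed",
                                 "variable cost per MSU deployment beyond the annual programme cost"),

    ## -- short-term patient costs -------------------------------------------
    conventional_transport_cost = p(450, "cost", "assumed",
                                    "EMS transport, conventional pathway", gamma_(0.15)),
    msu_transport_cost = p(450, "cost", "assumed",
                           "EMS transport in the rendezvous system (regular ambulance)", gamma_(0.15)),
    secondary_transfer_cost = p(700, "cost", "assumed",
                                "secondary interhospital transfer (conventional arm only)", gamma_(0.20)),
    secondary_transfer_prob = p(0.25, "probability", "assumed",
                                "probability of secondary transfer under conventional care", beta_(60)),
    acute_cost_by_mrs = p(
      stats::setNames(c(5000, 6500, 8500, 11000, 14000, 16500, 10000),
                      c(.mrs_labels, "death")),
      "cost", "assumed",
      "direct hospital cost of the acute ischemic stroke admission by 90-day mRS",
      gamma_(0.15)),
    acute_cost_tia = p(3000, "cost", "assumed", "acute admission cost, TIA", gamma_(0.15)),
    acute_cost_hemorrhagic = p(12000, "cost", "assumed", "acute admission cost, hemorrhagic stroke", gamma_(0.15)),
    acute_cost_mimic = p(1500, "cost", "assumed", "diagnostic workup cost, stroke mimic", gamma_(0.15)),

    ## -- long-term annual costs by mRS --------------------------------------
    lt_hc_annual_by_mrs = p(
      stats::setNames(c(0, 400, 1200, 3500, 8000, 12000), .mrs_labels),
      "cost", "assumed",
      "stroke-induced additional hospitalization days per year, healthcare perspective",
      gamma_(0.20)),
    lt_nursing_insurance_by_mrs = p(
      stats::setNames(c(0, 600, 2400, 7000, 14000, 20000), .mrs_labels),
      "cost", "assumed",
      "insurance-covered long-term home care / nursing, societal add-on", gamma_(0.20)),
    lt_nursing_family_by_mrs = p(
      stats::setNames(c(0, 400, 1600, 5000, 11000, 15000), .mrs_labels),
      "cost", "assumed",
      "family-covered nursing, societal add-on", gamma_(0.20)),
    gross_annual_wage = p(43200, "cost", "assumed",
                          "gross yearly earnings for the human capital approach"),
    employment_rate = p(0.72, "probability", "assumed",
                        "employment rate below the retirement cutoff"),
    ability_to_work_by_mrs = p(
      stats::setNames(c(1, 0.9, 0.7, 0.4, 0.1, 0), .mrs_labels),
      "fraction", "assumed", "residual ability to work by mRS"),
    retirement_age = p(67, "count", "assumed", "productivity losses apply below this age"),

    ## -- Markov model -------------------------------------------------------
    mrs_entry_conventional = p(
      stats::setNames(c(0.16, 0.18, 0.13, 0.15, 0.15, 0.08, 0.15),
                      c(.mrs_labels, "death")),
      "simplex", "assumed",
      "90-day mRS distribution, conventional care (dispatch-trial outcome data)",
      diri_(150)),
    mrs_entry_msu = p(
      stats::setNames(c(0.21, 0.20, 0.13, 0.14, 0.12, 0.06, 0.14),
                      c(.mrs_labels, "death")),
      "simplex", "assumed",
      "90-day mRS distribution, MSU-based care (dispatch-trial outcome data)",
      diri_(150)),
    utilities_by_mrs = p(
      stats::setNames(c(0.92, 0.86, 0.74, 0.56, 0.33, 0.12), .mrs_labels),
      "probability", "assumed",
      "German utility value set by mRS level", beta_(200)),
    mortality_by_mrs = p(
      stats::setNames(c(0.04, 0.05, 0.07, 0.11, 0.18, 0.30), .mrs_labels),
      "probability", "assumed",
      "annual all-cause death probability by mRS at cohort age", beta_(200)),
    recurrence_by_year = p(
      stats::setNames(c(0.08, 0.05, 0.04, 0.04, 0.04), paste0("year", 1:5)),
      "probability", "assumed",
      "annual stroke recurrence probability by year since index event", beta_(200)),
    nonis_utility = p(0.85, "probability", "assumed",
                      "annual utility of non-IS managed patients (identical across strategies)"),

    ## -- discrete-event oracle ----------------------------------------------
    service_time_hours = p(1.5, "count", "assumed",
                           "MSU occupation time per deployment (dispatch to availability)")
  )
}

#' Build the model parameter set
#'
#' Returns the full typed registry of model inputs: each parameter carries a
#' value (scalar or named vector, all money in 2021 euros, all rates annual),
#' a validation domain, a provenance tag (\code{"paper"} for values printed in
#' the source study's main text, \code{"assumed"} for shipped stand-ins for
#' its supplementary data, \code{"user"} after an override), a free-text note,
#' and an optional probabilistic sensitivity analysis distribution.
#'
#' @param overrides named list of parameter values replacing shipped defaults.
#'   Vector parameters must be replaced whole, with the original length.
#' @return An object of class \code{msu_params}.
#' @examples
#' p <- msu_parameters()
#' param_value(p, "discount_rate")
#' p2 <- msu_parameters(overrides = list(base_population = 500000))
#' @export
msu_parameters <- function(overrides = list()) {
  reg <- .default_registry()
  if (length(overrides)) {
    stopifnot(!is.null(names(overrides)), all(nzchar(names(overrides))))
    unknown <- setdiff(names(overrides), names(reg))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    for (nm in names(overrides)) {
      v <- overrides[[nm]]
      old <- reg[[nm]]$value
      if (length(v) != length(old))
        stop("override for '", nm, "' must have length ", length(old))
      if (!is.null(names(old))) names(v) <- names(old)
      reg[[nm]]$value <- v
      reg[[nm]]$provenance <- "user"
    }
  }
  out <- structure(reg, class = "msu_params")
  validate_parameters(out)
  out
}

#' Extract a parameter value
#'
#' @param params an \code{msu_params} object
#' @param name parameter name
#' @return the numeric value (scalar or named vector)
#' @export
param_value <- function(params, name) {
  stopifnot(inherits(params, "msu_params"))
  if (is.null(params[[name]])) stop("unknown parameter: ", name)
  params[[name]]$value
}

#' Validate a parameter set
#'
#' Checks that every required parameter is present and that each value lies in
#' its declared domain: probabilities and fractions in \code{[0, 1]},
#' simplexes nonnegative and summing to 1, costs/counts/rates nonnegative.
#'
#' @param params an \code{msu_params} object (or plain registry list)
#' @param schema optional schema as returned by \code{read_parameter_schema};
#'   defaults to the shipped schema structure derived from the registry.
#' @return invisibly \code{TRUE}; errors name every offending parameter.
#' @export
validate_parameters <- function(params, schema = NULL) {
  if (is.null(schema)) schema <- .registry_schema()
  missing <- setdiff(names(schema), names(params))
  if (length(missing))
    stop("missing required parameter(s): ", paste(missing, collapse = ", "))
  bad <- character(0)
  for (nm in names(schema)) {
    entry <- params[[nm]]
    v <- entry$value
    sc <- schema[[nm]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      bad <- c(bad, paste0(nm, " (non-finite value)")); next
    }
    if (length(v) != sc$length) {
      bad <- c(bad, paste0(nm, " (expected length ", sc$length, ")")); next
    }
    ok <- switch(sc$domain,
      probability = all(v >= 0 & v <= 1),
      fraction    = all(v >= 0 & v <= 1),
      simplex     = all(v >= 0) && abs(sum(v) - 1) < 1e-6,
      cost        = all(v >= 0),
      count       = all(v >= 0),
      rate        = all(v >= 0),
      real        = TRUE)
    if (!ok) bad <- c(bad, paste0(nm, " (out of domain '", sc$domain, "')"))
    psa <- entry$psa
    if (!is.null(psa) &&
        !psa$family %in% c("beta", "gamma", "dirichlet", "uniform", "lognormal"))
      bad <- c(bad, paste0(nm, " (unknown PSA family '", psa$family, "')"))
  }
  if (length(bad))
    stop("parameter validation failed: ", paste(bad, collapse = "; "))
  invisible(TRUE)
}

.registry_schema <- function() {
  reg <- .default_registry()
  lapply(reg, function(e) list(domain = e$domain, length = length(e$value),
                               required = TRUE))
}

#' Write the parameter schema to JSON
#'
#' @param path output path
#' @return invisibly \code{path}
#' @export
write_parameter_schema <- function(path) {
  jsonlite::write_json(.registry_schema(), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a parameter schema from JSON
#'
#' @param path schema file (defaults to the shipped schema)
#' @return a named schema list usable by \code{validate_parameters}
#' @export
read_parameter_schema <- function(path = system.file("extdata", "parameter_schema.json",
                                                     package = "msucea")) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Save a parameter set to a YAML file
#'
#' @param params an \code{msu_params} object
#' @param path output file
#' @return invisibly \code{path}
#' @export
write_msu_parameters <- function(params, path) {
  stopifnot(inherits(params, "msu_params"))
  ser <- lapply(unclass(params), function(e) {
    out <- list(value = as.numeric(e$value))
    if (!is.null(names(e$value))) out$names <- names(e$value)
    out$provenance <- e$provenance
    out$note <- e$note
    if (!is.null(e$psa)) out$psa <- e$psa
    out
  })
  yaml::write_yaml(list(parameters = ser), path, precision = 15)
  invisible(path)
}

#' Load a parameter set from a YAML file
#'
#' The file must contain every required parameter and validate against the
#' shipped schema; missing parameters and out-of-domain values are reported
#' by name.
#'
#' @param path a YAML file written by \code{write_msu_parameters} (or edited
#'   by hand in the same structure)
#' @return an \code{msu_params} object
#' @export
read_msu_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$parameters)) stop("not a parameter file (no 'parameters' key): ", path)
  reg <- lapply(raw$parameters, function(e) {
    v <- as.numeric(unlist(e$value))
    if (!is.null(e$names)) names(v) <- unlist(e$names)
    list(value = v,
         domain = if (is.null(e$domain)) NA_character_ else e$domain,
         provenance = e$provenance, note = e$note,
         psa = e$psa)
  })
  # attach domains from the registry (domain is schema metadata, not user data)
  defaults <- .default_registry()
  for (nm in intersect(names(reg), names(defaults)))
    reg[[nm]]$domain <- defaults[[nm]]$domain
  out <- structure(reg, class = "msu_params")
  validate_parameters(out)
  out
}

#' Provenance report
#'
#' @param params an \code{msu_params} object
#' @return a data.frame with one row per parameter: name, provenance, whether
#'   a PSA distribution is attached, and the source note.
#' @export
provenance_report <- function(params) {
  stopifnot(inherits(params, "msu_params"))
  data.frame(
    name = names(params),
    provenance = vapply(params, function(e) e$provenance, ""),
    psa = vapply(params, function(e) if (is.null(e$psa)) "" else e$psa$family, ""),
    note = vapply(params, function(e) e$note, ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.msu_params <- function(x, ...) {
  pr <- provenance_report(x)
  cat("MSU cost-effectiveness parameter set:", nrow(pr), "parameters\n")
  cat("  provenance:", paste(sprintf("%s=%d", names(table(pr$provenance)),
                                     as.integer(table(pr$provenance))),
                             collapse = ", "), "\n")
  cat("  with PSA distribution:", sum(nzchar(pr$psa)), "\n")
  invisible(x)
}

# -- PSA sampling ------------------------------------------------------------

.sample_one <- function(value, domain, psa) {
  fam <- psa$family
  v <- value
  if (fam == "beta") {
    n_eff <- psa$n_eff
    out <- v
    idx <- v > 0 & v < 1          # degenerate 0/1 kept fixed
    out[idx] <- stats::rbeta(sum(idx), v[idx] * n_eff, (1 - v[idx]) * n_eff)
    out
  } else if (fam == "gamma") {
    cv <- psa$cv
    shape <- 1 / cv^2
    out <- v
    idx <- v > 0                  # zero costs stay zero
    out[idx] <- stats::rgamma(sum(idx), shape = shape, scale = v[idx] / shape)
    out
  } else if (fam == "dirichlet") {
    conc <- psa$conc
    a <- v * conc
    g <- vapply(a, function(ai) if (ai <= 0) 0 else stats::rgamma(1, shape = ai), 0)
    g / sum(g)
  } else if (fam == "uniform") {
    hw <- psa$hw
    stats::runif(length(v), v * (1 - hw), v * (1 + hw))
  } else if (fam == "lognormal") {
    sdlog <- psa$sdlog
    v * stats::rlnorm(length(v), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else stop("invalid PSA distribution family: ", fam)
}

#' Draw one probabilistic-sensitivity-analysis parameter sample
#'
#' Parameters with an attached distribution are re-drawn (beta for
#' probabilities, gamma for costs, Dirichlet for mRS distributions);
#' parameters without one keep their base value.  Sampled values respect the
#' parameter's domain by construction.  A fixed seed gives an identical draw.
#'
#' @param params an \code{msu_params} object
#' @param seed integer seed; \code{NULL} uses the current RNG state
#' @return a new \code{msu_params} object with provenance preserved
#' @export
sample_parameters <- function(params, seed = NULL) {
  stopifnot(inherits(params, "msu_params"))
  if (!is.null(seed)) set.seed(seed)
  out <- unclass(params)
  for (nm in names(out)) {            # fixed registry order => reproducible
    e <- out[[nm]]
    if (is.null(e$psa)) next
    s <- .sample_one(e$value, e$domain, e$psa)
    names(s) <- names(e$value)
    out[[nm]]$value <- s
  }
  structure(out, class = "msu_params")
}
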