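# Report generation: CSV surfaces mirroring the base-case table, the
# mode/catchment grids and the PSA outputs, each traceable to a run manifest.

.write_manifest <- function(dir, command, params_path = NULL, seed = NULL,
                            outputs = character(0)) {
  manifest <- list(
    command = command,
    params_md5 = if (!is.null(params_path) && file.exists(params_path))
      unname(tools::md5sum(params_path)) else NA,
    seed = seed,
    package_version = as.character(utils::packageVersion("msucea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(dir, paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write a base-case report
#'
#' Runs the full pipeline for one configuration and writes a CSV with
#' per-strategy discounted costs and QALYs, incremental cost/effect, ICER and
#' net monetary benefit per perspective, plus the cascade and a run manifest.
#'
#' @param dir output directory (created if needed)
#' @param params an \code{msu_params} object
#' @param mode an \code{operating_mode} or label such as \code{"8x7"}
#' @param population catchment population
#' @param perspectives perspectives to report
#' @param params_path optional path of the parameter file used, recorded
#'   (hashed) in the manifest
#' @return invisibly the \code{msu_cea} fit
#' @export
write_base_case_report <- function(dir, params = msu_parameters(),
                                   mode = "8x7", population = NULL,
                                   perspectives = c("healthcare", "societal"),
                                   params_path = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fit <- msu_cea(params, mode, population, perspectives)
  rows <- do.call(rbind, lapply(names(fit$cea), function(p) {
    o <- fit$outcomes[[p]]; ce <- fit$cea[[p]]
    data.frame(perspective = p,
               cost_conventional = o$conventional$cost,
               qalys_conventional = o$conventional$qalys,
               cost_msu = o$msu$cost, qalys_msu = o$msu$qalys,
               delta_cost = ce$delta_cost, delta_qalys = ce$delta_qalys,
               icer = ce$icer, nmb = ce$nmb, wtp = ce$wtp)
  }))
  f1 <- file.path(dir, "base_case.csv")
  f2 <- file.path(dir, "cascade.csv")
  utils::write.csv(rows, f1, row.names = FALSE)
  utils::write.csv(as.data.frame(fit$cascade), f2, row.names = FALSE)
  .write_manifest(dir, "base_case", params_path, outputs = basename(c(f1, f2)))
  invisible(fit)
}

#' Write mode- and catchment-grid reports
#'
#' @param dir output directory
#' @param params an \code{msu_params} object
#' @param modes list of modes or labels (default: the 12-mode set)
#' @param populations vector of catchment populations
#' @param params_path optional parameter file path for the manifest
#' @return invisibly the \code{msu_scenario_grid}
#' @export
write_grid_report <- function(dir, params = msu_parameters(),
                              modes = default_mode_set(),
                              populations = param_value(params, "base_population"),
                              params_path = NULL) {
  if (!length(modes)) stop("empty mode list")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- scenario_grid(params, modes, populations)
  f <- file.path(dir, "scenario_grid.csv")
  utils::write.csv(grid, f, row.names = FALSE)
  .write_manifest(dir, "grid", params_path, outputs = basename(f))
  invisible(grid)
}

#' Write PSA reports (cost-effectiveness plane and acceptability curve)
#'
#' @param dir output directory
#' @param params an \code{msu_params} object
#' @param n Monte Carlo iterations
#' @param seed integer seed
#' @param wtp_grid thresholds for the acceptability curve
#' @param params_path optional parameter file path for the manifest
#' @return invisibly the \code{msu_psa}
#' @export
write_psa_report <- function(dir, params = msu_parameters(), n = 1000, seed = 1,
                             wtp_grid = seq(0, 150000, by = 1000),
                             params_path = NULL) {
  if (n <= 0) stop("n must be positive")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(params, n = n, seed = seed, wtp_grid = wtp_grid)
  f1 <- file.path(dir, "ce_plane.csv")
  f2 <- file.path(dir, "ceac.csv")
  f3 <- file.path(dir, "psa_summary.csv")
  utils::write.csv(psa$iterations, f1, row.names = FALSE)
  utils::write.csv(psa$ceac, f2, row.names = FALSE)
  utils::write.csv(data.frame(wtp = psa$wtp,
                              ce_fraction_healthcare = psa$ce_fraction["healthcare"],
                              ce_fraction_societal = psa$ce_fraction["societal"],
                              n = psa$n, seed = psa$seed),
                   f3, row.names = FALSE)
  .write_manifest(dir, "psa", params_path, seed = seed,
                  outputs = basename(c(f1, f2, f3)))
  invisible(psa)
}
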