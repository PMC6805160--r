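# End-to-end pipeline: simulate (or load) -> fit diagrams -> microscopic
# fits -> occupancy -> asymmetry, with a machine-readable JSON summary.

#' Run the full traffic-analysis pipeline
#'
#' Executes the analysis stages in order and writes every table plus a JSON
#' summary into `out_dir`.  Stages can be toggled; by default all run.  Data
#' either come from the synthetic generator (seeded, so re-running with the
#' same configuration is byte-identical) or from CSV files.
#'
#' The configuration list accepts:
#' \describe{
#'   \item{seed}{integer RNG seed (required for simulation).}
#'   \item{stages}{character subset of `simulate`, `fit_diagram`,
#'     `fit_micro`, `occupancy`, `asymmetry` (default: all).}
#'   \item{out_dir}{output directory (default `"."`); created if needed.}
#'   \item{flow_csv, tracked_csv}{input paths; when given, these replace the
#'     simulate stage for the corresponding table.}
#'   \item{generator}{list of [generator_config()] arguments.}
#'   \item{params}{list of [micro_params()] arguments.}
#'   \item{n_tracked}{number of tracked records to simulate (default 8000).}
#'   \item{bin_width}{density bin width for the binned summary (default 0.5).}
#'   \item{span}{loess span for travel-time curves (default 0.75).}
#' }
#'
#' @param config a named list as above, or the path to a YAML/JSON file
#'   (see [read_pipeline_config()]).
#' @return Invisibly, the summary list (also written to
#'   `out_dir/summary.json`): fitted parameters with standard errors, the
#'   AIC/Akaike-weight table, the limit flow and plateau estimate, the
#'   occupancy table and the response-surface coefficients, plus the seed
#'   and config hash.
#' @examples
#' \donttest{
#' out <- run_pipeline(list(seed = 1, out_dir = tempdir(),
#'                          generator = list(duration = 900),
#'                          n_tracked = 2000))
#' out$diagram$selected
#' }
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.list(config)) ant_config_error("run_pipeline: config must be a list")
  all_stages <- c("simulate", "fit_diagram", "fit_micro", "occupancy",
                  "asymmetry")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad))
    ant_config_error(sprintf("run_pipeline: unknown stage(s): %s",
                             paste(bad, collapse = ", ")))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  # the destination directory is not part of the analysis configuration
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  gen_args <- config$generator %||% list()
  if (!is.null(seed)) gen_args$seed <- seed
  gcfg <- do.call(generator_config, gen_args)
  params <- do.call(micro_params, config$params %||% list())
  n_tracked <- config$n_tracked %||% 8000
  bin_width <- config$bin_width %||% 0.5
  span <- config$span %||% 0.75

  summary <- list(tool = "anttraffic", version = pkg_version(),
                  seed = seed, config_hash = hash)
  obs <- tracked <- NULL

  if (!is.null(config$flow_csv)) {
    obs <- read_flow_density(config$flow_csv)
  } else if ("simulate" %in% stages) {
    obs <- generate_macroscopic(gcfg, params)
    write_flow_density(obs, file.path(out_dir, "flow_density.csv"),
                       seed = seed, hash = hash)
  }
  if (!is.null(config$tracked_csv)) {
    tracked <- read_tracked(config$tracked_csv)
  } else if ("simulate" %in% stages) {
    tcfg <- gcfg
    tcfg$seed <- if (is.null(seed)) NULL else seed + 1L
    tracked <- generate_tracked(n_tracked, params = params, config = tcfg)
    write_tracked(tracked, file.path(out_dir, "tracked.csv"),
                  seed = tcfg$seed, hash = hash)
  }

  if ("fit_diagram" %in% stages) {
    if (is.null(obs))
      ant_data_error("run_pipeline: fit_diagram needs flow/density data")
    fits <- lapply(c("two_phase", "greenshields", "pipes_munjal",
                     "underwood"), fit_diagram, obs = obs)
    sel <- akaike_weights(fits)
    tab <- as.data.frame(sel)
    utils::write.csv(tab, file.path(out_dir, "diagram_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(bin_summary(obs, bin_width),
                     file.path(out_dir, "bin_summary.csv"), row.names = FALSE)
    summary$diagram <- list(
      table = tab, selected = tab$model[1],
      fits = lapply(sel, function(f)
        list(estimates = as.list(f$estimates), se = as.list(f$se),
             sse = f$sse, aic = f$aic, akaike_weight = f$akaike_weight)))
  }

  if ("fit_micro" %in% stages) {
    if (is.null(tracked))
      ant_data_error("run_pipeline: fit_micro needs tracked-ant data")
    cr <- fit_contact_rate(tracked)
    tt <- fit_travel_time(tracked)
    sf <- fit_speed_model(tracked, fixed = params)
    curves <- travel_time_curves(tracked, span = span)
    utils::write.csv(curves, file.path(out_dir, "travel_time_curves.csv"),
                     row.names = FALSE)
    summary$micro <- list(
      contact_rate = list(slope = cr$slope, se = cr$se,
                          r_squared = cr$r_squared, n = cr$n),
      travel_time = list(T0 = tt$T0, dT = tt$dT, se = as.list(tt$se),
                         r_squared = tt$r_squared, n = tt$n),
      speed_model = list(estimates = as.list(sf$estimates),
                         se = as.list(sf$se), sse = sf$sse, n = sf$n),
      limit_flow = limit_flow(sf$params),
      plateau_flow = predict_flow(14, sf$params))
  }

  if ("occupancy" %in% stages) {
    occ <- species_occupancy()
    utils::write.csv(occ, file.path(out_dir, "occupancy.csv"),
                     row.names = FALSE)
    summary$occupancy <- occ
  }

  if ("asymmetry" %in% stages) {
    if (is.null(obs))
      ant_data_error("run_pipeline: asymmetry needs flow/density data")
    surf <- response_surface(asymmetry_series(obs))
    utils::write.csv(
      data.frame(term = names(surf$beta), beta = unname(surf$beta)),
      file.path(out_dir, "asymmetry.csv"), row.names = FALSE)
    summary$asymmetry <- list(beta = as.list(surf$beta),
                              r_squared = surf$r_squared, n = surf$n)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
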