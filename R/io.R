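# CSV readers/writers for the two record tables, plus config file support.
# Every file written carries a comment header with the package version, the
# config hash and the seed, so outputs are traceable and byte-reproducible.

flow_cols    <- c("t", "k", "n_out", "n_in", "width", "q", "experiment_id")
tracked_cols <- c("direction", "k_local", "C", "T", "uturn")

pkg_version <- function()
  as.character(utils::packageVersion("anttraffic"))

#' Hash a configuration for output provenance
#'
#' MD5 of the canonical JSON serialisation of a configuration list, used to
#' stamp outputs so a result file can be matched to the exact settings that
#' produced it.
#'
#' @param config any serialisable list.
#' @return 32-character hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), tf)
  unname(tools::md5sum(tf))
}

write_records <- function(df, path, required, seed = NULL, hash = NULL) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  # full-precision formatting so write/read round-trips are exact
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# anttraffic %s", pkg_version()),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else format(seed)),
    sprintf("# config_hash: %s", if (is.null(hash)) "NA" else hash)), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_records <- function(path, required, coltypes, what) {
  if (!file.exists(path))
    ant_data_error(sprintf("%s: file not found: %s", what, path))
  if (file.size(path) == 0) {
    warning(sprintf("%s: %s is empty", what, path))
    return(as.data.frame(stats::setNames(
      lapply(coltypes, function(f) f(character(0))), required)))
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", encoding = "UTF-8"),
    error = function(e) ant_data_error(sprintf(
      "%s: cannot parse %s (%s)", what, path, conditionMessage(e))))
  if (nrow(df) == 0 && ncol(df) == 0) {
    warning(sprintf("%s: %s is empty", what, path))
    df <- as.data.frame(stats::setNames(
      lapply(coltypes, function(f) f(character(0))), required))
    return(df)
  }
  miss <- setdiff(required, names(df))
  if (length(miss))
    ant_data_error(sprintf("%s: %s is missing column(s): %s", what, path,
                           paste(miss, collapse = ", ")))
  for (i in seq_along(required)) {
    col <- required[i]
    conv <- coltypes[[i]](df[[col]])
    if (any(is.na(conv) & !is.na(df[[col]])))
      ant_data_error(sprintf("%s: %s column '%s' has malformed values",
                             what, path, col))
    df[[col]] <- conv
  }
  df
}

#' Read and write flow/density record tables
#'
#' Comma-delimited UTF-8 tables with one row per second and the fixed
#' columns `t, k, n_out, n_in, width, q, experiment_id`.  Leading `#`
#' comment lines carry provenance (package version, config hash, seed) and
#' are skipped on read.  Unknown extra columns are preserved.  Numeric
#' columns are written at full precision, so a write/read round trip
#' reproduces the data exactly.
#'
#' @param path file path.
#' @param obs data frame of flow/density records.
#' @param seed,hash provenance stamps for the file header (the seed defaults
#'   to the `seed` attribute the generator attaches).
#' @return `read_flow_density` returns the data frame (empty, with a
#'   warning, for an empty file); the writers return the path invisibly.
#' @name flow_density_io
#' @export
read_flow_density <- function(path) {
  read_records(path, flow_cols,
               list(as.numeric, as.numeric, as.integer, as.integer,
                    as.numeric, as.numeric, as.character),
               "read_flow_density")
}

#' @rdname flow_density_io
#' @export
write_flow_density <- function(obs, path, seed = attr(obs, "seed"),
                               hash = NULL) {
  need_cols(obs, flow_cols, "write_flow_density")
  write_records(obs, path, flow_cols, seed, hash)
}

#' Read and write tracked-ant record tables
#'
#' Comma-delimited UTF-8 tables with one row per tracked crossing and the
#' fixed columns `direction, k_local, C, T, uturn`; same provenance header
#' and round-trip guarantees as [read_flow_density()].
#'
#' @inheritParams flow_density_io
#' @param tracked data frame of tracked-ant records.
#' @name tracked_io
#' @export
read_tracked <- function(path) {
  df <- read_records(path, tracked_cols,
                     list(as.character, as.numeric, as.integer, as.numeric,
                          function(x) as.logical(x)),
                     "read_tracked")
  df
}

#' @rdname tracked_io
#' @export
write_tracked <- function(tracked, path, seed = attr(tracked, "seed"),
                          hash = NULL) {
  need_cols(tracked, tracked_cols, "write_tracked")
  write_records(tracked, path, tracked_cols, seed, hash)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML (or JSON; YAML is a superset) key-value file into the list
#' [run_pipeline()] accepts.
#'
#' @param path path to the config file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    ant_config_error(sprintf("config file not found: %s", path))
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    ant_config_error(sprintf("cannot parse config %s: %s", path,
                             conditionMessage(e))))
  if (!is.list(cfg))
    ant_config_error(sprintf("config %s must be a key-value mapping", path))
  cfg
}
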