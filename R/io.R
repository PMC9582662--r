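#' Read and write endpoint tables
#'
#' Endpoint tables travel as plain CSV with the header `cell_id, x1, y1, x2,
#' y2, duration_h, unit`; the identical schema serves experimental-style
#' input and simulation output. Writing then reading reproduces the numeric
#' columns to full precision.
#'
#' @param records An [endpoint_records()] table.
#' @param path File path.
#' @return `read_endpoints()` returns a validated [endpoint_records()]
#'   table; `write_endpoints()` returns `path` invisibly.
#' @export
write_endpoints <- function(records, path) {
  records <- validate_endpoints(records)
  utils::write.csv(as.data.frame(records)[, c("cell_id", "x1", "y1", "x2",
                                              "y2", "duration_h", "unit")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_endpoints
#' @export
read_endpoints <- function(path) {
  if (!file.exists(path)) stop("no such endpoint file: ", path)
  validate_endpoints(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a trajectory table
#'
#' Long-format CSV, one row per cell per step (see [trajectory_df()]).
#'
#' @param traj A `sim_trajectory`.
#' @param path File path.
#' @param run_id Identifier for the `run_id` column.
#' @export
write_trajectory <- function(traj, path, run_id = 1L) {
  utils::write.csv(trajectory_df(traj, run_id), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a migration summary as JSON
#'
#' Serialises the output of [analyze_endpoints()] (directionality, speed
#' statistics, anodal fraction, counts and the 36 x 9 polar histogram) to a
#' JSON file.
#'
#' @param summary A list as returned by [analyze_endpoints()].
#' @param path File path.
#' @export
write_summary <- function(summary, path) {
  out <- summary
  out$histogram <- unclass(out$histogram)
  attributes(out$histogram) <- list(dim = dim(summary$histogram))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line (`#` comments and blank lines ignored).
#' Keys mirror the [model_params()] field names; unknown keys are an error
#' so that typos fail loudly. In addition to the model parameters the keys
#' `strength_V_per_m` (converted through [dimensionless_magnitude()] and
#' overriding `E0`) and `orientation_deg` (field orientation) are accepted.
#'
#' @param path Path to the configuration file.
#' @return A named list of numeric values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1])
    val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) stop("non-numeric value for config key '", key, "'")
    out[[key]] <- val
  }
  allowed <- c(names(formals(model_params)), "strength_V_per_m",
               "orientation_deg")
  unknown <- setdiff(names(out), allowed)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  out
}

#' Build model parameters from a configuration list
#'
#' @param config A list as returned by [read_config()].
#' @return A list with elements `params` ([model_params()]) and
#'   `orientation` (field angle in radians).
#' @export
params_from_config <- function(config) {
  orientation <- 0
  if (!is.null(config$orientation_deg)) {
    orientation <- config$orientation_deg * pi / 180
    config$orientation_deg <- NULL
  }
  if (!is.null(config$strength_V_per_m)) {
    config$E0 <- dimensionless_magnitude(config$strength_V_per_m)
    config$strength_V_per_m <- NULL
  }
  list(params = do.call(model_params, config), orientation = orientation)
}

#' Write sweep results
#'
#' Two CSVs: the long per-run table and the per-value aggregates.
#'
#' @param sweep A `sweep_result` from [run_sweep()].
#' @param results_path,aggregates_path Output file paths.
#' @export
write_sweep <- function(sweep, results_path, aggregates_path) {
  utils::write.csv(sweep$results, results_path, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sweep$aggregates, aggregates_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(results_path, aggregates_path))
}
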