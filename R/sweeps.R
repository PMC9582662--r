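#' Replicate simulation runs
#'
#' Runs `n_runs` independent simulations with seeds `base_seed + 0 ..
#' n_runs - 1`, analyses each endpoint table, and pools the records, mirroring
#' the protocol in which each reported polar plot cumulates ten separate
#' runs.
#'
#' @param params A [model_params()] object.
#' @param n_runs Number of replicates; >= 1.
#' @param base_seed Seed of the first run.
#' @param calib Optional [calibration_constants()] applied to every run.
#' @return A list with `summary` (data.frame: `run`, `seed`, `phi`,
#'   `mean_speed`, `max_speed`, `anodal_fraction`) and `endpoints` (pooled
#'   [endpoint_records()] with a `run` column).
#' @export
replicate_runs <- function(params, n_runs = 10, base_seed = params$seed,
                           calib = NULL) {
  stopifnot(n_runs >= 1)
  rows <- vector("list", n_runs)
  eps <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    seed <- as.integer(base_seed) + r - 1L
    tr <- run_simulation(params, seed = seed)
    ep <- endpoints_from_trajectory(tr, calib)
    s <- analyze_endpoints(ep)
    rows[[r]] <- data.frame(run = r, seed = seed, phi = s$phi,
                            mean_speed = s$mean_speed,
                            max_speed = max(migration_speed(ep)),
                            anodal_fraction = s$anodal_fraction)
    ep$run <- r
    eps[[r]] <- ep
  }
  list(summary = do.call(rbind, rows),
       endpoints = do.call(rbind, eps))
}

#' Specify a parameter sweep
#'
#' @param parameter One of `"r_a"`, `"eta"`, `"N"`, `"E0"`. For a cell
#'   density sweep pass `parameter = "N"`; values below 1 are interpreted as
#'   the published density labels and mapped to cell counts
#'   (0.02 -> 25, 0.03 -> 35, 0.04 -> 45, 0.06 -> 65).
#' @param values Ordered, non-empty vector of parameter values.
#' @param base_params [model_params()] into which each value is substituted.
#' @param n_runs Replicates per value; >= 1.
#' @param base_seed Seed of the first run of each value.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter, values, base_params = model_params(),
                       n_runs = 10, base_seed = base_params$seed) {
  if (!parameter %in% c("r_a", "eta", "N", "E0"))
    stop("unknown sweep parameter: ", parameter)
  if (!length(values)) stop("sweep needs at least one value")
  stopifnot(n_runs >= 1)
  labels <- values
  if (parameter == "N" && all(values < 1)) {
    map <- c("0.02" = 25, "0.03" = 35, "0.04" = 45, "0.06" = 65)
    key <- format(values)
    if (!all(key %in% names(map)))
      stop("unknown density label(s): ",
           paste(key[!key %in% names(map)], collapse = ", "))
    values <- unname(map[key])
  }
  structure(list(parameter = parameter, values = values, labels = labels,
                 base_params = base_params, n_runs = n_runs,
                 base_seed = base_seed),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' For each value in the spec, substitutes it into the base parameter set,
#' performs [replicate_runs()], and aggregates the per-run summaries by
#' value (median, quartiles, mean, standard deviation), the box-plot-style
#' reduction used for sweep figures. Fully reproducible from
#' `(spec, base_seed)`.
#'
#' @param spec A [sweep_spec()].
#' @param calib Optional [calibration_constants()] applied to every run.
#' @return A list of class `sweep_result` with `results` (long data.frame:
#'   `parameter`, `value`, `label`, `run`, `seed`, `phi`, `mean_speed`,
#'   `max_speed`, `anodal_fraction`) and `aggregates` (one row per value with
#'   `*_median`, `*_q25`, `*_q75`, `*_mean`, `*_sd` for `phi`, `mean_speed`
#'   and `anodal_fraction`).
#' @export
run_sweep <- function(spec, calib = NULL) {
  stopifnot(inherits(spec, "sweep_spec"))
  res <- vector("list", length(spec$values))
  for (v in seq_along(spec$values)) {
    p <- do.call(update_params,
                 c(list(spec$base_params),
                   stats::setNames(list(spec$values[v]), spec$parameter)))
    rr <- replicate_runs(p, spec$n_runs, spec$base_seed, calib)
    res[[v]] <- cbind(parameter = spec$parameter, value = spec$values[v],
                      label = spec$labels[v], rr$summary)
  }
  results <- do.call(rbind, res)
  agg_one <- function(x) c(median = stats::median(x),
                           q25 = unname(stats::quantile(x, 0.25)),
                           q75 = unname(stats::quantile(x, 0.75)),
                           mean = mean(x), sd = stats::sd(x))
  aggregates <- do.call(rbind, lapply(split(results, results$value), function(g) {
    out <- data.frame(parameter = g$parameter[1], value = g$value[1],
                      label = g$label[1], n_runs = nrow(g))
    for (m in c("phi", "mean_speed", "anodal_fraction")) {
      a <- agg_one(g[[m]])
      names(a) <- paste(m, names(a), sep = "_")
      out <- cbind(out, as.data.frame(as.list(a)))
    }
    out
  }))
  aggregates <- aggregates[order(match(aggregates$value, spec$values)), ]
  rownames(aggregates) <- NULL
  structure(list(spec = spec, results = results, aggregates = aggregates),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep over %s (%d values x %d runs)\n",
              x$spec$parameter, length(x$spec$values), x$spec$n_runs))
  print(x$aggregates[, c("parameter", "value", "phi_median",
                         "mean_speed_median", "anodal_fraction_median")])
  invisible(x)
}
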