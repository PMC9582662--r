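#' Simulation-to-physical calibration constants
#'
#' Conversion between simulation units and physical units for the endpoint
#' analysis: how many micrometres one simulation length unit represents and
#' how many hours a full run of `T` steps spans.
#'
#' The nominal calibration takes the cell radius (1 length unit) as 50 um --
#' half of the roughly 100 um diameter of a spread osteoblast -- and a run as
#' one 7 h observation window. Because the model's unstimulated cells are
#' close to ballistic over a run, the nominal constants yield sham speeds far
#' above the few-um/h scale of tracked osteoblasts, so the recommended,
#' default route is the empirical anchor of [calibrate_to_sham()]: the length
#' conversion is set so that the mean endpoint speed of unstimulated
#' (sham) runs equals the observed sham speed, and all stimulated conditions
#' reuse that same factor.
#'
#' @param microns_per_unit Micrometres per simulation length unit; > 0.
#' @param hours_per_run Hours represented by one full run; > 0.
#' @return An object of class `calibration_constants`.
#' @export
calibration_constants <- function(microns_per_unit = 50, hours_per_run = 7) {
  stopifnot(microns_per_unit > 0, hours_per_run > 0)
  structure(list(microns_per_unit = microns_per_unit,
                 hours_per_run = hours_per_run),
            class = "calibration_constants")
}

#' @export
print.calibration_constants <- function(x, ...) {
  cat(sprintf("calibration: 1 length unit = %.4g um, 1 run = %g h\n",
              x$microns_per_unit, x$hours_per_run))
  invisible(x)
}

#' Anchor the calibration to the sham migration speed
#'
#' Runs `n_runs` unstimulated simulations (`E0 = 0`, other parameters as
#' given), measures the mean endpoint speed in simulation units per hour, and
#' returns the calibration whose length conversion maps that mean onto
#' `anchor_um_per_h` (the observed mean speed of sham-stimulated osteoblasts,
#' about 3 um/h). Stimulated conditions analysed with the returned constants
#' therefore report speeds on the experimental scale.
#'
#' @param params A [model_params()] object (its `E0` is ignored).
#' @param n_runs Number of sham replicates to average.
#' @param base_seed First seed; run `r` uses `base_seed + r - 1`.
#' @param anchor_um_per_h Target sham mean speed in um/h.
#' @param hours_per_run Hours represented by one run.
#' @return A [calibration_constants()] object with attribute
#'   `"sham_mean_speed_sim"` (sim units per hour).
#' @export
calibrate_to_sham <- function(params, n_runs = 10, base_seed = params$seed,
                              anchor_um_per_h = 3, hours_per_run = 7) {
  sham <- update_params(params, E0 = 0)
  d <- unlist(lapply(seq_len(n_runs) - 1L, function(r) {
    tr <- run_simulation(sham, seed = base_seed + r)
    ep <- endpoints_from_trajectory(tr)
    displacement(ep)
  }))
  mean_speed_sim <- mean(d) / hours_per_run
  structure(calibration_constants(anchor_um_per_h / mean_speed_sim,
                                  hours_per_run),
            sham_mean_speed_sim = mean_speed_sim)
}

#' Endpoint records of a simulated trajectory
#'
#' Reduces a trajectory to the two-timepoint records of the migration
#' analysis: one row per cell built from the unwrapped start and end
#' positions (so displacement is not folded by the periodic box). With a
#' calibration the coordinates are converted to micrometres and the duration
#' to hours; without one the records stay in simulation units over
#' `hours_per_run` hours.
#'
#' @param traj A `sim_trajectory`.
#' @param calib Optional [calibration_constants()].
#' @param hours_per_run Duration assigned when `calib` is `NULL`.
#' @return An [endpoint_records()] table.
#' @export
endpoints_from_trajectory <- function(traj, calib = NULL, hours_per_run = 7) {
  last <- dim(traj$unwrapped)[1]
  f <- if (is.null(calib)) 1 else calib$microns_per_unit
  hrs <- if (is.null(calib)) hours_per_run else calib$hours_per_run
  endpoint_records(cell_id = seq_len(dim(traj$unwrapped)[2]),
                   x1 = f * traj$unwrapped[1, , 1],
                   y1 = f * traj$unwrapped[1, , 2],
                   x2 = f * traj$unwrapped[last, , 1],
                   y2 = f * traj$unwrapped[last, , 2],
                   duration_h = hrs,
                   unit = if (is.null(calib)) "sim" else "um")
}

#' Summary statistics of an endpoint table
#'
#' The standard migration summary: directionality order parameter (from the
#' endpoint angles), mean and median speed, fraction of anodally directed
#' cells, counts, and the 36 x 9 polar histogram. Zero-displacement records
#' are excluded from the angular statistics (directionality, anodal
#' fraction, histogram) but contribute speed 0 to the speed statistics.
#'
#' @inheritParams displacement
#' @return A list with elements `phi`, `mean_speed`, `median_speed`,
#'   `anodal_fraction`, `n`, `n_zero` and `histogram`.
#' @export
analyze_endpoints <- function(records) {
  records <- validate_endpoints(records)
  ang <- migration_angle(records)
  spd <- migration_speed(records)
  list(phi = directionality(ang),
       mean_speed = mean(spd),
       median_speed = stats::median(spd),
       anodal_fraction = mean(is_anodal(ang[!is.na(ang)])),
       n = nrow(records),
       n_zero = sum(is.na(ang)),
       histogram = polar_histogram(records))
}
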