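#' Specify a synthetic endpoint-table fixture
#'
#' Describes a cohort of tracked cells with a controllable directional bias
#' and speed distribution, emulating the two-timepoint centroid tables
#' produced by cell tracking. Used to exercise the analysis layer without
#' any experimental data.
#'
#' @param n_cells Number of cells; >= 1.
#' @param mean_direction_deg Centre of the angular distribution, degrees.
#' @param concentration von Mises concentration; 0 draws angles uniformly.
#' @param speed_mean,speed_sd Mean and standard deviation of the (truncated
#'   at zero) normal speed distribution, um/h.
#' @param duration_h Observation window in hours; > 0.
#' @param seed RNG seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_cells = 100, mean_direction_deg = 180,
                         concentration = 0, speed_mean = 3, speed_sd = 1,
                         duration_h = 7, seed = 1L) {
  stopifnot(n_cells >= 1, concentration >= 0, speed_mean >= 0,
            speed_sd >= 0, duration_h > 0)
  structure(list(n_cells = as.integer(n_cells),
                 mean_direction_deg = mean_direction_deg,
                 concentration = concentration,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 duration_h = duration_h, seed = as.integer(seed)),
            class = "fixture_spec")
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 falls
# back to the uniform distribution on the circle.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (u[2] < cc * (2 - cc) || log(cc) - log(u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

#' Generate a synthetic endpoint table
#'
#' Draws migration angles from a von Mises distribution centred on
#' `mean_direction_deg` (uniform when `concentration = 0`) and speeds from a
#' normal distribution truncated at zero (constant when `speed_sd = 0`).
#' Start positions are scattered uniformly in a 500 um square; end positions
#' follow from `x2 = x1 + d cos(angle)`, `y2 = y1 + d sin(angle)` with
#' `d = speed * duration`.
#'
#' @param spec A [fixture_spec()].
#' @return An [endpoint_records()] table in micrometre units.
#' @examples
#' ep <- generate_endpoints(fixture_spec(n_cells = 50, concentration = 8))
#' directionality(migration_angle(ep))
#' @export
generate_endpoints <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  ang <- rvonmises(n, spec$mean_direction_deg * pi / 180, spec$concentration)
  if (spec$speed_sd == 0) {
    spd <- rep(spec$speed_mean, n)
  } else {
    spd <- numeric(n)
    got <- 0L
    while (got < n) {
      draw <- stats::rnorm(n - got, spec$speed_mean, spec$speed_sd)
      keep <- draw[draw >= 0]
      if (length(keep)) {
        spd[(got + 1L):(got + length(keep))] <- keep
        got <- got + length(keep)
      }
    }
  }
  d <- spd * spec$duration_h
  x1 <- stats::runif(n, 0, 500)
  y1 <- stats::runif(n, 0, 500)
  endpoint_records(cell_id = seq_len(n),
                   x1 = x1, y1 = y1,
                   x2 = x1 + d * cos(ang), y2 = y1 + d * sin(ang),
                   duration_h = spec$duration_h, unit = "um")
}
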