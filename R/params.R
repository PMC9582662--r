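#' Model parameters for an electrotaxis simulation
#'
#' Bundles every tunable quantity of the self-propelled-particle model in
#' simulation units (the cell radius `R` is the unit of length, one update is
#' the unit of time). The defaults are the reference parameter set used
#' throughout: 35 cells of radius 1 migrating for 140 steps on a periodic
#' 50 x 50 domain under a uniform DC field of dimensionless magnitude 0.014
#' (the calibration equivalent of 160 V/m), with anodal polarity.
#'
#' @param R Cell radius (length units). The basic length scale; > 0.
#' @param v0 Active migration speed per step; >= 0.
#' @param k Soft-core repulsion constant; >= 0. Overlapping cells push apart
#'   with force `k * (2R - r_ij)` proportional to their overlap.
#' @param nu Friction factor converting the repulsive force into displacement
#'   (cell-substrate interaction); >= 0.
#' @param mu Electrical mobility converting the sensed field into
#'   displacement; >= 0.
#' @param eta Angular noise strength; >= 0. Each step every heading receives
#'   an independent kick `eta * xi` with `xi` uniform on `[-pi/2, pi/2]`.
#' @param r_a Alignment radius: a cell averages the heading vectors of all
#'   cells strictly closer than `r_a` (itself included); >= 0. The default
#'   `2 * R` restricts alignment to touching cells.
#' @param r_e Field-sensing radius: the cell sums the field vectors at all
#'   lattice points strictly closer than `r_e`; > 0.
#' @param E0 Dimensionless magnitude of the uniform DC field; >= 0. See
#'   [dimensionless_magnitude()] for the V/m calibration.
#' @param polarity `+1` for cathode-directed coupling, `-1` (default) for the
#'   anode-directed response observed in osteoblasts.
#' @param N Number of cells; >= 1.
#' @param L Side of the square periodic domain; must exceed `4 * R`.
#' @param T Number of time steps; >= 1.
#' @param grid_spacing Lattice constant of the field grid (length units).
#' @param init_radius Radius of the circular region around the domain centre
#'   in which cells are initially placed; at most `L / 2`.
#' @param seed Integer seed from which all randomness of a run flows.
#'
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params()           # reference parameter set
#' p35 <- model_params(E0 = 0.038, T = 140)
#' @export
model_params <- function(R = 1, v0 = 0.1, k = 0.3, nu = 0.1, mu = 0.04,
                         eta = 0.05, r_a = 2, r_e = 2, E0 = 0.014,
                         polarity = -1, N = 35, L = 50, T = 140,
                         grid_spacing = 1, init_radius = 10, seed = 1L) {
  p <- list(R = R, v0 = v0, k = k, nu = nu, mu = mu, eta = eta,
            r_a = r_a, r_e = r_e, E0 = E0, polarity = polarity,
            N = as.integer(N), L = L, T = as.integer(T),
            grid_spacing = grid_spacing, init_radius = init_radius,
            seed = as.integer(seed))
  validate_params(p)
  structure(p, class = "model_params")
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in names(p)) {
    if (!num1(p[[f]])) stop("parameter '", f, "' must be a single finite number")
  }
  stopifnot_msg(p$R > 0, "R must be > 0")
  stopifnot_msg(p$v0 >= 0, "v0 must be >= 0")
  stopifnot_msg(p$k >= 0, "k must be >= 0")
  stopifnot_msg(p$nu >= 0, "nu must be >= 0")
  stopifnot_msg(p$mu >= 0, "mu must be >= 0")
  stopifnot_msg(p$eta >= 0, "eta must be >= 0")
  stopifnot_msg(p$r_a >= 0, "r_a must be >= 0")
  stopifnot_msg(p$r_e > 0, "r_e must be > 0")
  stopifnot_msg(p$E0 >= 0, "E0 must be >= 0")
  stopifnot_msg(p$polarity %in% c(-1, 1), "polarity must be +1 or -1")
  stopifnot_msg(p$N >= 1, "N must be >= 1")
  stopifnot_msg(p$L > 4 * p$R, "L must be > 4 * R")
  stopifnot_msg(p$T >= 0, "T must be >= 0")
  stopifnot_msg(p$grid_spacing > 0, "grid_spacing must be > 0")
  stopifnot_msg(p$init_radius > 0 && p$init_radius <= p$L / 2,
                "init_radius must be in (0, L/2]")
  invisible(p)
}

stopifnot_msg <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' @export
print.model_params <- function(x, ...) {
  cat("Electrotaxis model parameters (simulation units)\n")
  cat(sprintf("  cells: N = %d, radius R = %g, active speed v0 = %g\n",
              x$N, x$R, x$v0))
  cat(sprintf("  interactions: k = %g, nu = %g, alignment r_a = %g, noise eta = %g\n",
              x$k, x$nu, x$r_a, x$eta))
  cat(sprintf("  field: E0 = %g, mobility mu = %g, sensing r_e = %g, polarity %+d, grid spacing %g\n",
              x$E0, x$mu, x$r_e, x$polarity, x$grid_spacing))
  cat(sprintf("  domain: %g x %g periodic, init radius %g, T = %d steps, seed %d\n",
              x$L, x$L, x$init_radius, x$T, x$seed))
  invisible(x)
}

#' Update a parameter set
#'
#' Returns a copy of `params` with the named fields replaced and the result
#' re-validated. Convenience for parameter sweeps.
#'
#' @param params A [model_params()] object.
#' @param ... Named fields to replace.
#' @return A `model_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "model_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- unclass(params)
  p[names(repl)] <- repl
  p$N <- as.integer(p$N); p$T <- as.integer(p$T); p$seed <- as.integer(p$seed)
  validate_params(p)
  structure(p, class = "model_params")
}
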