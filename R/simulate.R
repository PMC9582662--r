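#' Minimum-image displacement on the periodic domain
#'
#' Vector from `a` to `b` folded to the nearest periodic copy, so that each
#' component lies in `[-L/2, L/2)`.
#'
#' @param a,b Numeric length-2 points, or n x 2 matrices of points.
#' @param L Side of the periodic square domain; > 0.
#' @return Displacement vector(s) with the same shape as the inputs.
#' @examples
#' periodic_displacement(c(49, 0), c(1, 0), 50)  # c(2, 0)
#' @export
periodic_displacement <- function(a, b, L) {
  stopifnot(L > 0)
  ((b - a + L / 2) %% L) - L / 2
}

# Deterministic pseudo-random unit direction for a coincident pair, seeded by
# (min(i,j), max(i,j), t) so that re-runs stay bit-identical without touching
# the simulation RNG stream.
coincident_direction <- function(i, j, t) {
  lo <- min(i, j); hi <- max(i, j)
  h <- sin(lo * 12.9898 + hi * 78.233 + t * 37.719) * 43758.5453
  ang <- 2 * pi * (h - floor(h))
  c(cos(ang), sin(ang))
}

#' Place the initial cell population
#'
#' Cells are dropped uniformly at random inside the disk of radius
#' `init_radius` around the domain centre `(L/2, L/2)`; each placement is
#' re-drawn (up to 1000 times) until its centre is at least `2R` from every
#' cell already placed, so the population starts without overlaps. If the
#' retry budget is exhausted (disk too small for `N` cells) the overlap is
#' accepted with a warning; the repulsion force resolves it within a few
#' steps. Headings are i.i.d. uniform on `[0, 2 pi)`.
#'
#' Draws from the current RNG stream: call `set.seed()` first (or use
#' [run_simulation()], which seeds from `params$seed`).
#'
#' @param params A [model_params()] object.
#' @return A `swarm_state`: list with `time_index = 0`, `positions` (N x 2,
#'   wrapped into `[0, L)`), `headings` (length N, radians), `speed` (`v0`)
#'   and `L`.
#' @export
init_population <- function(params) {
  p <- validate_params(params)
  N <- p$N
  centre <- c(p$L / 2, p$L / 2)
  pos <- matrix(NA_real_, N, 2)
  relaxed <- FALSE
  for (i in seq_len(N)) {
    for (try in seq_len(1000L)) {
      rr <- p$init_radius * sqrt(stats::runif(1))
      aa <- stats::runif(1, 0, 2 * pi)
      cand <- centre + rr * c(cos(aa), sin(aa))
      if (i == 1L) break
      d <- periodic_displacement(pos[seq_len(i - 1L), , drop = FALSE],
                                 matrix(cand, i - 1L, 2, byrow = TRUE), p$L)
      if (min(d[, 1]^2 + d[, 2]^2) >= (2 * p$R)^2) break
      if (try == 1000L) relaxed <- TRUE
    }
    pos[i, ] <- cand %% p$L
  }
  if (relaxed)
    warning("init_radius too small for ", N,
            " non-overlapping cells; residual overlaps accepted")
  structure(list(time_index = 0L, positions = pos,
                 headings = stats::runif(N, 0, 2 * pi),
                 speed = p$v0, L = p$L),
            class = "swarm_state")
}

#' @export
print.swarm_state <- function(x, ...) {
  cat(sprintf("swarm_state: %d cells at t = %d on [0, %g)^2\n",
              nrow(x$positions), x$time_index, x$L))
  invisible(x)
}

#' Neighbours of a cell within a radius
#'
#' Indices of all cells whose minimum-image distance from cell `i` is
#' strictly less than `radius`. Ties at exactly the radius are excluded, so
#' `radius = 0` returns no neighbours even with `include_self`.
#'
#' @param state A `swarm_state`.
#' @param i Cell index.
#' @param radius Search radius; >= 0.
#' @param include_self Should `i` itself be returned (when in range)?
#' @return Integer vector of cell indices.
#' @export
neighbors_within <- function(state, i, radius, include_self = FALSE) {
  stopifnot(radius >= 0)
  d <- periodic_displacement(
    matrix(state$positions[i, ], nrow(state$positions), 2, byrow = TRUE),
    state$positions, state$L)
  sel <- which(d[, 1]^2 + d[, 2]^2 < radius^2)
  if (!include_self) sel <- sel[sel != i]
  sel
}

#' Pairwise soft-core repulsion
#'
#' Force on cell `i` from cell `j`: zero unless the cells overlap
#' (minimum-image distance `r_ij < 2R`), otherwise of magnitude
#' `k * (2R - r_ij)` directed away from `j`, i.e. proportional to the overlap
#' and pushing the cells apart. Exactly coincident centres (undefined
#' direction) are pushed along a deterministic pseudo-random direction seeded
#' by `(i, j, time_index)` so runs remain reproducible.
#'
#' @param i,j Distinct cell indices.
#' @param state A `swarm_state`.
#' @param params A [model_params()] object.
#' @return Length-2 force vector acting on cell `i`.
#' @export
pair_repulsion <- function(i, j, state, params) {
  stopifnot(i != j)
  dv <- periodic_displacement(state$positions[i, ], state$positions[j, ],
                              state$L)
  r <- sqrt(sum(dv^2))
  if (r >= 2 * params$R) return(c(0, 0))
  if (r == 0) {
    dir <- coincident_direction(i, j, state$time_index)
    if (i > j) dir <- -dir
    return(params$k * 2 * params$R * dir)
  }
  # unit vector from j towards i pushes i away from j
  params$k * (2 * params$R - r) * (-dv / r)
}

#' Total repulsion on a cell
#'
#' Vector sum of [pair_repulsion()] over every other cell overlapping cell
#' `i` (minimum-image distance < `2R`).
#'
#' @inheritParams pair_repulsion
#' @return Length-2 force vector.
#' @export
total_repulsion <- function(i, state, params) {
  f <- c(0, 0)
  for (j in neighbors_within(state, i, 2 * params$R)) {
    f <- f + pair_repulsion(i, j, state, params)
  }
  f
}

# Vectorised repulsion for all cells at once; agrees with total_repulsion.
repulsion_all <- function(positions, t, params) {
  N <- nrow(positions)
  if (N == 1L) return(matrix(0, 1, 2))
  # dx[i, j] = min-image x-component of (r_j - r_i); same for dy
  dx <- periodic_displacement(matrix(positions[, 1], N, N),
                              matrix(positions[, 1], N, N, byrow = TRUE), params$L)
  dy <- periodic_displacement(matrix(positions[, 2], N, N),
                              matrix(positions[, 2], N, N, byrow = TRUE), params$L)
  d <- sqrt(dx^2 + dy^2)
  ov <- d < 2 * params$R & d > 0
  diag(ov) <- FALSE
  w <- matrix(0, N, N)
  w[ov] <- params$k * (2 * params$R - d[ov]) / d[ov]
  # force on i = sum_j k(2R - d) * (r_i - r_j)/d = -sum_j w * (dx, dy)
  out <- cbind(-rowSums(w * dx), -rowSums(w * dy))
  co <- which(d == 0 & !diag(TRUE, N), arr.ind = TRUE)
  if (nrow(co)) {
    for (r in seq_len(nrow(co))) {
      i <- co[r, 1]; j <- co[r, 2]
      dir <- coincident_direction(i, j, t)
      if (i > j) dir <- -dir
      out[i, ] <- out[i, ] + params$k * 2 * params$R * dir
    }
  }
  out
}

# Alignment resultants: rows = sum of heading unit vectors over all cells
# strictly within r_a (self included through the zero self-distance).
alignment_sums <- function(positions, headings, r_a, L) {
  N <- nrow(positions)
  dx <- periodic_displacement(matrix(positions[, 1], N, N),
                              matrix(positions[, 1], N, N, byrow = TRUE), L)
  dy <- periodic_displacement(matrix(positions[, 2], N, N),
                              matrix(positions[, 2], N, N, byrow = TRUE), L)
  A <- (dx^2 + dy^2) < r_a^2
  cbind(A %*% cos(headings), A %*% sin(headings))
}

#' Neighbour-aligned heading of one cell
#'
#' The alignment rule: the new heading is the argument of the vector sum of
#' the heading unit vectors of all cells strictly within `r_a` of cell `i`
#' (including `i` itself), plus the angular noise term `eta * xi`. If the
#' neighbour set is empty (only possible when `r_a = 0`) or the vector sum
#' vanishes, the cell's current heading is used in place of the argument.
#'
#' This is the pure alignment kernel; inside [step_swarm()] the mechanical
#' forces also enter the heading resultant (see the package vignette).
#'
#' @inheritParams pair_repulsion
#' @param xi Noise draw, uniform on `[-pi/2, pi/2]`.
#' @return New heading angle in radians.
#' @export
alignment_heading <- function(i, state, params, xi = 0) {
  s <- alignment_sums(state$positions, state$headings, params$r_a, state$L)[i, ]
  base <- if (sum(s^2) < 1e-24) state$headings[i] else atan2(s[2], s[1])
  base + params$eta * xi
}

#' Advance the swarm by one time step
#'
#' Synchronous update evaluated entirely on the time-`t` state. Each cell's
#' position advances by its active displacement plus the force displacements
#' of the overdamped dynamics,
#' `r' = r + v0 * s + nu * F + mu * D`, wrapped into `[0, L)`. Each heading
#' relaxes towards the resultant of its neighbourhood's consensus direction
#' and the same mechanical displacements,
#' `theta' = arg(u + nu * F + mu * D) + eta * xi`, where `u` is the unit
#' vector along the alignment sum (the cell's own heading when the sum is
#' empty or vanishes) and `xi` is uniform on `[-pi/2, pi/2]`. The new heading
#' takes effect in the active displacement of the next step.
#'
#' Consumes `N` noise draws from the current RNG stream in cell order.
#'
#' @param state A `swarm_state` at time `t`.
#' @param field A [uniform_field()] grid.
#' @param params A [model_params()] object.
#' @return The `swarm_state` at time `t + 1`, with attribute
#'   `"displacement"` holding the N x 2 unwrapped step displacements.
#' @export
step_swarm <- function(state, field, params) {
  pos <- state$positions
  th <- state$headings
  N <- nrow(pos)
  F_rep <- repulsion_all(pos, state$time_index, params)
  D_fld <- field_force_all(pos, field, params$r_e, params$polarity)
  force <- params$nu * F_rep + params$mu * D_fld

  disp <- cbind(params$v0 * cos(th), params$v0 * sin(th)) + force
  dimnames(disp) <- NULL

  a <- alignment_sums(pos, th, params$r_a, state$L)
  an <- sqrt(a[, 1]^2 + a[, 2]^2)
  ok <- an > 1e-12
  u <- cbind(cos(th), sin(th))          # fallback: own heading direction
  u[ok, ] <- a[ok, , drop = FALSE] / an[ok]
  h <- u + force
  hn <- h[, 1]^2 + h[, 2]^2
  new_th <- ifelse(hn > 1e-24, atan2(h[, 2], h[, 1]), th)
  new_th <- new_th + params$eta * stats::runif(N, -pi / 2, pi / 2)

  structure(list(time_index = state$time_index + 1L,
                 positions = (pos + disp) %% state$L,
                 headings = new_th,
                 speed = state$speed, L = state$L),
            class = "swarm_state",
            displacement = disp)
}

#' Run a full simulation
#'
#' Seeds the RNG from `seed`, places the population with
#' [init_population()] and applies [step_swarm()] `T` times. Positions are
#' recorded both wrapped into the periodic box and unwrapped (cumulative
#' displacements), so endpoint displacements are not truncated by the
#' boundary. The same seed reproduces the trajectory bit-exactly.
#'
#' @param params A [model_params()] object.
#' @param field Optional [uniform_field()] grid; built from `params`
#'   (`L`, `grid_spacing`, `E0`, orientation 0) when `NULL`.
#' @param seed RNG seed; defaults to `params$seed`.
#' @return A `sim_trajectory`: list with `params`, `seed`, `wrapped` and
#'   `unwrapped` position arrays of dim `(T+1, N, 2)`, and `headings` of dim
#'   `(T+1, N)`.
#' @examples
#' tr <- run_simulation(model_params(N = 5, T = 20))
#' dim(tr$unwrapped)  # 21 x 5 x 2
#' @export
run_simulation <- function(params, field = NULL, seed = params$seed) {
  p <- validate_params(params)
  if (is.null(field))
    field <- uniform_field(p$L, spacing = p$grid_spacing, E0 = p$E0)
  set.seed(seed)
  state <- init_population(params)
  N <- p$N
  wrapped <- array(NA_real_, c(p$T + 1L, N, 2))
  unwrapped <- array(NA_real_, c(p$T + 1L, N, 2))
  headings <- matrix(NA_real_, p$T + 1L, N)
  wrapped[1, , ] <- state$positions
  unwrapped[1, , ] <- state$positions
  headings[1, ] <- state$headings
  for (t in seq_len(p$T)) {
    state <- step_swarm(state, field, params)
    wrapped[t + 1L, , ] <- state$positions
    unwrapped[t + 1L, , ] <- unwrapped[t, , ] + attr(state, "displacement")
    headings[t + 1L, ] <- state$headings
  }
  structure(list(params = params, seed = seed, wrapped = wrapped,
                 unwrapped = unwrapped, headings = headings),
            class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf("sim_trajectory: %d cells, %d steps, E0 = %g, seed %d\n",
              dim(x$wrapped)[2], dim(x$wrapped)[1] - 1L, x$params$E0, x$seed))
  invisible(x)
}

#' Long-format trajectory table
#'
#' One row per cell per recorded time point, with wrapped and unwrapped
#' coordinates and the heading, suitable for CSV export.
#'
#' @param traj A `sim_trajectory`.
#' @param run_id Identifier written into the `run_id` column.
#' @return A data.frame with columns `run_id`, `cell_id`, `t`, `x_wrapped`,
#'   `y_wrapped`, `x_unwrapped`, `y_unwrapped`, `theta_rad`.
#' @export
trajectory_df <- function(traj, run_id = 1L) {
  steps <- dim(traj$wrapped)[1]
  N <- dim(traj$wrapped)[2]
  data.frame(run_id = run_id,
             cell_id = rep(seq_len(N), each = steps),
             t = rep(seq_len(steps) - 1L, N),
             x_wrapped = as.vector(traj$wrapped[, , 1]),
             y_wrapped = as.vector(traj$wrapped[, , 2]),
             x_unwrapped = as.vector(traj$unwrapped[, , 1]),
             y_unwrapped = as.vector(traj$unwrapped[, , 2]),
             theta_rad = as.vector(traj$headings))
}
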