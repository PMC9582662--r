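#' Convert an experimental field strength to the dimensionless magnitude
#'
#' The model's field magnitude is calibrated so that 0.014 corresponds to an
#' applied DC field of 160 V/m; other strengths scale linearly (e.g. 436 V/m
#' is 0.014 * 436/160 = 0.0385, reported as 0.038 at the conventional
#' 3-decimal display precision).
#'
#' @param strength_V_per_m Applied field strength in V/m; >= 0.
#' @param digits Decimal places used for the returned (display) value;
#'   `NULL` returns the unrounded magnitude.
#' @return Dimensionless field magnitude.
#' @examples
#' dimensionless_magnitude(160)  # 0.014
#' dimensionless_magnitude(436)  # 0.038
#' @export
dimensionless_magnitude <- function(strength_V_per_m, digits = 3) {
  if (!is.numeric(strength_V_per_m) || any(!is.finite(strength_V_per_m)))
    stop("field strength must be a finite number")
  if (any(strength_V_per_m < 0)) stop("field strength must be >= 0")
  e0 <- 0.014 * strength_V_per_m / 160
  if (is.null(digits)) e0 else round(e0, digits)
}

#' Build a uniform DC field on a square lattice
#'
#' The field is defined at the points of a regular square lattice covering the
#' periodic domain `[0, L)^2`; every point carries the same vector
#' `E0 * (cos(orientation), sin(orientation))`. The default orientation 0
#' stores the field along +x; the anodal response is produced by the cell
#' polarity `p = -1`, which places the anode at 180 degrees in the analysis
#' convention.
#'
#' @param L Side of the square domain.
#' @param spacing Lattice constant; `L` should be (close to) a multiple.
#' @param E0 Field magnitude at every lattice point.
#' @param orientation Field angle in radians (default 0, along +x).
#' @return An object of class `field_grid` with elements `L`, `spacing`,
#'   `E0`, `orientation`, `coords` (K x 2 lattice coordinates) and `vectors`
#'   (K x 2 field vectors), flagged `uniform` for the fast sensing path.
#' @examples
#' g <- uniform_field(50, spacing = 1, E0 = 0.014)
#' nrow(g$coords)  # 2500 lattice points
#' @export
uniform_field <- function(L, spacing = 1, E0 = 0.014, orientation = 0) {
  stopifnot(L > 0, spacing > 0)
  n_side <- round(L / spacing)
  if (abs(n_side * spacing - L) > 1e-8 * L)
    warning("L is not a multiple of spacing; lattice truncated to ",
            n_side, " points per side")
  ax <- seq(0, by = spacing, length.out = n_side)
  coords <- as.matrix(expand.grid(x = ax, y = ax))
  dimnames(coords) <- NULL
  vec <- E0 * c(cos(orientation), sin(orientation))
  structure(list(L = L, spacing = spacing, E0 = E0, orientation = orientation,
                 coords = coords,
                 vectors = matrix(vec, nrow(coords), 2, byrow = TRUE),
                 uniform = TRUE),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("field_grid: %d lattice points, spacing %g on [0, %g)^2\n",
              nrow(x$coords), x$spacing, x$L))
  cat(sprintf("  %s field, magnitude E0 = %g, orientation %g rad\n",
              if (isTRUE(x$uniform)) "uniform" else "non-uniform",
              x$E0, x$orientation))
  invisible(x)
}

# Count of lattice points strictly within r_e of each position (uniform grid
# fast path). Enumerates candidate lattice offsets around each cell, which is
# exact because the lattice tiles the torus.
lattice_count <- function(positions, spacing, r_e) {
  m <- ceiling(r_e / spacing)
  off <- as.matrix(expand.grid(u = -m:m, v = -m:m)) * spacing
  fx <- positions[, 1] %% spacing
  fy <- positions[, 2] %% spacing
  cnt <- integer(nrow(positions))
  for (j in seq_len(nrow(off))) {
    cnt <- cnt + ((off[j, 1] - fx)^2 + (off[j, 2] - fy)^2 < r_e^2)
  }
  cnt
}

# Vectorised field force for all cells: p * sum of E_k over lattice points
# with minimum-image distance < r_e. Returns an N x 2 matrix.
field_force_all <- function(positions, grid, r_e, polarity) {
  if (isTRUE(grid$uniform)) {
    cnt <- lattice_count(positions, grid$spacing, r_e)
    if (all(cnt == 0L))
      warning("no lattice point within r_e of any cell (spacing > r_e?); zero field force")
    vec <- grid$E0 * c(cos(grid$orientation), sin(grid$orientation))
    return(polarity * cbind(cnt * vec[1], cnt * vec[2]))
  }
  out <- matrix(0, nrow(positions), 2)
  for (i in seq_len(nrow(positions))) {
    d <- periodic_displacement(matrix(positions[i, ], nrow(grid$coords), 2,
                                      byrow = TRUE),
                               grid$coords, grid$L)
    sel <- d[, 1]^2 + d[, 2]^2 < r_e^2
    if (!any(sel)) {
      warning("no lattice point within r_e of cell ", i, "; zero field force")
      next
    }
    out[i, ] <- polarity * colSums(grid$vectors[sel, , drop = FALSE])
  }
  out
}

#' Field force sensed by one cell
#'
#' Sums the lattice field vectors at all grid points strictly closer than
#' `r_e` to the cell centre (minimum-image distance on the periodic domain)
#' and applies the cell polarity: `p * sum E_k`. With the default anodal
#' polarity `p = -1` and a +x field this force points towards the anode
#' (-x direction).
#'
#' @param i Cell index.
#' @param state A [swarm_state] as returned by [init_population()].
#' @param grid A [uniform_field()] grid.
#' @param params A [model_params()] object (`r_e`, `polarity`).
#' @return Length-2 force vector.
#' @export
local_field <- function(i, state, grid, params) {
  as.numeric(field_force_all(state$positions[i, , drop = FALSE], grid,
                             params$r_e, params$polarity))
}
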