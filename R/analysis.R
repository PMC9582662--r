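#' Build an endpoint-record table
#'
#' The data unit of the two-timepoint migration analysis: one row per cell
#' with its centroid at the start (`x1`, `y1`) and end (`x2`, `y2`) of the
#' observation and the elapsed time in hours. The same schema is used for
#' experimental-style tracking tables (coordinates in micrometres,
#' `unit = "um"`) and for raw simulation endpoints (`unit = "sim"`).
#'
#' @param cell_id Cell labels.
#' @param x1,y1,x2,y2 Start and end centroid coordinates.
#' @param duration_h Elapsed time in hours; > 0.
#' @param unit `"um"` or `"sim"`.
#' @return A data.frame of class `endpoint_records`.
#' @export
endpoint_records <- function(cell_id, x1, y1, x2, y2, duration_h,
                             unit = "um") {
  df <- data.frame(cell_id = cell_id, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                   duration_h = duration_h,
                   unit = unit, stringsAsFactors = FALSE)
  validate_endpoints(df)
}

validate_endpoints <- function(df) {
  need <- c("cell_id", "x1", "y1", "x2", "y2", "duration_h")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("endpoint table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"unit" %in% names(df)) df$unit <- "um"
  num <- c("x1", "y1", "x2", "y2", "duration_h")
  for (cl in num) {
    if (!is.numeric(df[[cl]]) || any(!is.finite(df[[cl]])))
      stop("endpoint column '", cl, "' must be finite numeric")
  }
  if (any(df$duration_h <= 0)) stop("duration_h must be > 0")
  if (!all(df$unit %in% c("um", "sim"))) stop("unit must be 'um' or 'sim'")
  class(df) <- union("endpoint_records", class(df))
  df
}

#' Endpoint migration distance
#'
#' Euclidean distance between the start and end centroids,
#' `sqrt((x1 - x2)^2 + (y1 - y2)^2)`. For simulation input the coordinates
#' must be unwrapped so the periodic box does not truncate the displacement
#' (see [endpoints_from_trajectory()]).
#'
#' @param records An endpoint table ([endpoint_records()]).
#' @return Numeric vector of distances, in the table's length unit.
#' @export
displacement <- function(records) {
  sqrt((records$x1 - records$x2)^2 + (records$y1 - records$y2)^2)
}

#' Endpoint migration angle
#'
#' Full-quadrant angle of the displacement vector, `atan2(y2 - y1, x2 - x1)`
#' mapped to degrees in `[0, 360)`. Records with zero displacement have no
#' direction and return `NA`; they are excluded from all angular statistics.
#'
#' @inheritParams displacement
#' @return Numeric vector of angles in degrees, `NA` for zero displacement.
#' @export
migration_angle <- function(records) {
  dx <- records$x2 - records$x1
  dy <- records$y2 - records$y1
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  ang[dx == 0 & dy == 0] <- NA_real_
  ang
}

#' Endpoint migration speed
#'
#' Endpoint distance divided by the elapsed time. Meaningful in micrometres
#' per hour once the table is in physical units (`unit = "um"`).
#'
#' @inheritParams displacement
#' @return Numeric vector of speeds.
#' @export
migration_speed <- function(records) {
  displacement(records) / records$duration_h
}

#' Angular sector of a migration angle
#'
#' The circle is divided into 36 sectors of 10 degrees: sector `s` covers
#' `[(s-1)*10, s*10)`. Sectors 10-27 span the anodal half (90-270 degrees),
#' sectors 1-9 and 28-36 the cathodal half.
#'
#' @param angle Angle(s) in degrees, in `[0, 360)`.
#' @return Integer sector index in 1..36 (`NA` propagates).
#' @export
sector_index <- function(angle) {
  bad <- !is.na(angle) & (angle < 0 | angle >= 360)
  if (any(bad)) stop("angles must lie in [0, 360)")
  as.integer(pmin(floor(angle / 10) + 1, 36))
}

#' Is a migration angle anode-directed?
#'
#' `TRUE` when the angle lies strictly between 90 and 270 degrees, the
#' half-plane containing the anode (at 180 degrees in this convention). The
#' boundary angles 90 and 270 are assigned to the cathodal side, consistent
#' with the sector table (sectors 1-9 and 28-36 cathodal).
#'
#' @param angle Angle(s) in degrees, in `[0, 360)`.
#' @return Logical vector (`NA` propagates).
#' @export
is_anodal <- function(angle) {
  bad <- !is.na(angle) & (angle < 0 | angle >= 360)
  if (any(bad)) stop("angles must lie in [0, 360)")
  angle > 90 & angle < 270
}

#' Speed score of a migration speed
#'
#' Nine speed bins of 2 um/h spanning 0-18 um/h: bin `b` covers
#' `[(b-1)*2, b*2)`; speeds of 18 um/h and above clamp into bin 9.
#'
#' @param speed Speed(s) in um/h; >= 0.
#' @return Integer bin index in 1..9.
#' @export
speed_bin <- function(speed) {
  if (any(speed < 0, na.rm = TRUE)) stop("speeds must be >= 0")
  as.integer(pmin(floor(speed / 2) + 1, 9))
}

#' Polar migration histogram
#'
#' Cross-tabulates the endpoint records into 36 angular sectors x 9 speed
#' bins and converts the counts to percentages of the cells with non-zero
#' displacement (which sum to 100). Zero-displacement records carry no
#' direction; they are excluded from the table and reported separately.
#'
#' @inheritParams displacement
#' @return A 36 x 9 matrix of percentages with attributes `n_cells` (cells
#'   binned) and `n_zero` (zero-displacement records excluded).
#' @export
polar_histogram <- function(records) {
  if (nrow(records) == 0) stop("no endpoint records")
  ang <- migration_angle(records)
  spd <- migration_speed(records)
  keep <- !is.na(ang)
  if (!any(keep)) stop("no record with positive displacement")
  tab <- matrix(0, 36, 9,
                dimnames = list(sector = NULL, speed_bin = NULL))
  idx <- cbind(sector_index(ang[keep]), speed_bin(spd[keep]))
  for (r in seq_len(nrow(idx))) tab[idx[r, 1], idx[r, 2]] <-
      tab[idx[r, 1], idx[r, 2]] + 1
  structure(100 * tab / sum(keep),
            n_cells = sum(keep), n_zero = sum(!keep))
}

#' Directionality order parameter
#'
#' Mean cosine of the migration angles: `+1` for perfect cathodal alignment
#' (0 degrees), `-1` for perfect anodal alignment (180 degrees), and about 0
#' for isotropic or field-orthogonal movement. `NA` angles
#' (zero-displacement records) are dropped.
#'
#' @param angles_deg Migration angles in degrees.
#' @return The order parameter, in `[-1, 1]`.
#' @examples
#' directionality(c(180, 180))  # -1
#' directionality(c(90, 270))   # 0
#' @export
directionality <- function(angles_deg) {
  angles_deg <- angles_deg[!is.na(angles_deg)]
  if (!length(angles_deg)) stop("no angles to average")
  mean(cos(angles_deg * pi / 180))
}

#' Instantaneous-heading directionality
#'
#' Variant of [directionality()] computed from the cells' final heading
#' vectors rather than from endpoint displacement angles. Useful to compare
#' the internal polarity of the swarm with the endpoint estimator used for
#' experimental tables.
#'
#' @param traj A `sim_trajectory`.
#' @return Mean cosine of the final headings.
#' @export
heading_directionality <- function(traj) {
  mean(cos(traj$headings[nrow(traj$headings), ]))
}
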