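#' Dense 2-D pheromone field
#'
#' A pheromone field is a dense, non-negative grid of pheromone units that
#' proxies trail pheromone by accumulated ant passages: every second an ant
#' marks the equivalent of one square millimetre of substrate with one unit
#' of pheromone. Grid rows index y and columns index x; cell `(i, j)` has its
#' centre at `origin + (c(j, i) - 0.5) * cell_size`, with `origin` the
#' lower-left corner of cell `(1, 1)`. Evaporation is exponential with a
#' configurable half-life (`Inf` = no evaporation).
#'
#' @param grid numeric matrix of non-negative pheromone units.
#' @param cell_size cell edge length in mm (default 1, matching the
#'   1 unit / mm^2 / s deposition calibration).
#' @param origin numeric length-2, (x, y) in mm of the lower-left corner of
#'   the first cell.
#' @param time field timestamp in seconds since trial start.
#' @param half_life evaporation half-life in seconds, or `Inf`.
#' @return An object of class `pheromone_field`.
#' @export
pheromone_field <- function(grid, cell_size = 1, origin = c(0, 0), time = 0,
                            half_life = Inf) {
  if (!is.matrix(grid) || !is.numeric(grid))
    stop("`grid` must be a numeric matrix")
  if (anyNA(grid) || any(grid < 0))
    stop("pheromone values must be non-negative and non-missing")
  if (length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(half_life) != 1 || half_life <= 0)
    stop("`half_life` must be positive (use Inf for no evaporation)")
  structure(
    list(grid = grid, cell_size = cell_size,
         origin = as.numeric(origin[1:2]), time = time,
         half_life = half_life),
    class = "pheromone_field")
}

#' @export
print.pheromone_field <- function(x, ...) {
  cat(sprintf(
    "<pheromone_field> %d x %d cells of %g mm, t = %g s, half-life = %s\n",
    nrow(x$grid), ncol(x$grid), x$cell_size, x$time,
    if (is.finite(x$half_life)) paste0(x$half_life, " s") else "Inf"))
  cat(sprintf("  total = %.4g units, max = %.4g units\n",
              sum(x$grid), max(x$grid)))
  invisible(x)
}

field_extent <- function(field) {
  list(xlim = field$origin[1] + c(0, ncol(field$grid)) * field$cell_size,
       ylim = field$origin[2] + c(0, nrow(field$grid)) * field$cell_size)
}

#' Deposit pheromone on occupied cells
#'
#' Increments each occupied cell by `dq` pheromone units. Occupancy is an
#' indicator: a cell listed more than once in `cells` (e.g. two ants
#' overlapping in the same frame) is incremented once.
#'
#' @param field a [pheromone_field()].
#' @param cells two-column matrix of (row, column) cell indices.
#' @param dq deposit increment per occupied cell, in pheromone units. The
#'   default, 1/25, is one 25-Hz frame of marking by one ant whose footprint
#'   covers a single 1 mm^2 cell.
#' @return The updated field.
#' @export
deposit <- function(field, cells, dq = 1 / 25) {
  stopifnot(inherits(field, "pheromone_field"))
  if (length(cells) == 0) return(field)
  cells <- matrix(as.integer(cells), ncol = 2)
  bad <- cells[, 1] < 1 | cells[, 1] > nrow(field$grid) |
    cells[, 2] < 1 | cells[, 2] > ncol(field$grid)
  if (any(bad)) {
    b <- which(bad)[1]
    stop(sprintf("footprint cell (%d, %d) lies outside the grid",
                 cells[b, 1], cells[b, 2]))
  }
  cells <- cells[!duplicated(cells[, 1] + nrow(field$grid) * cells[, 2]), ,
                 drop = FALSE]
  field$grid[cells] <- field$grid[cells] + dq
  field
}

#' Advance field time, applying exponential evaporation
#'
#' Every cell is multiplied by `2^(-dt / half_life)` (a no-op when the
#' half-life is infinite) and the field timestamp advances by `dt`. The decay
#' is applied in closed form, so advancing by `dt` in one call or in many is
#' identical.
#'
#' @param field a [pheromone_field()].
#' @param dt elapsed time in seconds, `>= 0`.
#' @export
advance_time <- function(field, dt) {
  stopifnot(inherits(field, "pheromone_field"))
  if (dt < 0) stop("`dt` must be non-negative")
  if (is.finite(field$half_life) && dt > 0)
    field$grid <- field$grid * 2^(-dt / field$half_life)
  field$time <- field$time + dt
  field
}

#' Rescale all pheromone values
#'
#' Multiplies every cell by a positive factor. Sector sums are linear, so
#' this rescales every query by the same factor; the Weber contrast
#' `(C_L - C_R) / (C_L + C_R)` is invariant under it.
#'
#' @param field a [pheromone_field()].
#' @param factor positive multiplier.
#' @export
scale_field <- function(field, factor) {
  stopifnot(inherits(field, "pheromone_field"))
  if (length(factor) != 1 || !is.finite(factor) || factor <= 0)
    stop("`factor` must be a single positive number")
  field$grid <- field$grid * factor
  field
}

#' Total pheromone in a circular sector ahead of an ant
#'
#' Sums grid values over cells whose centres fall inside the circular sector
#' of the given radius spanning `[heading, heading + 2 * half_angle]` for the
#' left sector and `[heading - 2 * half_angle, heading)` for the right
#' (degrees, anticlockwise positive; a cell centre exactly on the heading ray
#' belongs to the left sector). Parts of the sector beyond the grid
#' contribute 0.
#'
#' @param field a [pheromone_field()].
#' @param pos numeric length-2 (x, y) position in mm; must lie within the
#'   grid extent.
#' @param heading heading in degrees (0 = +x axis, anticlockwise positive).
#' @param side `"left"` or `"right"`.
#' @param radius sector radius in mm (default 10 mm = 1 cm).
#' @param half_angle half the sector opening in degrees (default 45, i.e. a
#'   90-degree sector).
#' @return Pheromone units (a single number).
#' @export
sector_sum <- function(field, pos, heading, side = c("left", "right"),
                       radius = 10, half_angle = 45) {
  stopifnot(inherits(field, "pheromone_field"))
  side <- match.arg(side)
  if (radius <= 0) stop("`radius` must be positive")
  if (half_angle <= 0 || half_angle > 90)
    stop("`half_angle` must be in (0, 90]")
  ext <- field_extent(field)
  if (pos[1] < ext$xlim[1] || pos[1] > ext$xlim[2] ||
      pos[2] < ext$ylim[1] || pos[2] > ext$ylim[2])
    stop(sprintf("position (%g, %g) is outside the grid", pos[1], pos[2]))
  if (side == "left")
    sector_sum_cpp(field$grid, field$cell_size, field$origin[1],
                   field$origin[2], pos[1], pos[2], heading,
                   0, 2 * half_angle, TRUE, TRUE, radius)
  else
    sector_sum_cpp(field$grid, field$cell_size, field$origin[1],
                   field$origin[2], pos[1], pos[2], heading,
                   -2 * half_angle, 0, TRUE, FALSE, radius)
}

# ---------------------------------------------------------------------------
# Deposit streams: rasterized trajectories as a time-ordered stream of
# (time, cell, dq) increments with per-frame occupancy deduplication.
# ---------------------------------------------------------------------------

# Internal: rasterize trajectories into a deduplicated deposit stream.
# Footprint = cells whose centre is within `footprint_radius` of the sample
# point; per-cell increment = frame interval / footprint cell count, so each
# ant deposits 1 unit-equivalent per second in total. A cell covered by
# several ants in the same frame is incremented once (occupancy indicator).
deposit_stream <- function(traj, cell_size, origin, dim_rc, footprint_radius,
                           frame_rate) {
  ord <- order(traj$t_s, traj$ant_id)
  traj <- traj[ord, , drop = FALSE]
  fp <- traj_footprints_cpp(traj$x_mm, traj$y_mm, dim_rc[1], dim_rc[2],
                            cell_size, origin[1], origin[2], footprint_radius)
  n_cells <- fp$n_cells[fp$sample]
  t_s <- traj$t_s[fp$sample]
  frame <- round(t_s * frame_rate)
  key <- frame * (dim_rc[1] * dim_rc[2] + 1) + fp$cell
  keep <- !duplicated(key)
  list(t = t_s[keep], cell = fp$cell[keep],
       dq = (1 / frame_rate) / n_cells[keep])
}

auto_extent <- function(traj, cell_size, pad = 12) {
  xlim <- c(floor(min(traj$x_mm) - pad), ceiling(max(traj$x_mm) + pad))
  ylim <- c(floor(min(traj$y_mm) - pad), ceiling(max(traj$y_mm) + pad))
  list(origin = c(xlim[1], ylim[1]),
       dim_rc = c(ceiling(diff(ylim) / cell_size),
                  ceiling(diff(xlim) / cell_size)))
}

#' Build a pheromone field from trajectories
#'
#' Replays ant passages as deposits (1 pheromone-unit-equivalent per ant per
#' second, spread over a disc footprint around each tracked point) up to time
#' `until`, with exact exponential evaporation.
#'
#' @param traj trajectory data frame with columns `ant_id, t_s, x_mm, y_mm`.
#' @param cell_size grid cell edge in mm.
#' @param extent optional list with `origin` (x, y of the lower-left corner)
#'   and `dim_rc` (rows, columns); derived from the data when `NULL`.
#' @param half_life evaporation half-life in seconds, or `Inf`.
#' @param footprint_radius radius in mm of the disc footprint rasterized
#'   around each trajectory sample (default 1 mm).
#' @param frame_rate sampling rate of the trajectories in Hz.
#' @param until build the field as of this time (seconds); defaults to the
#'   last sample time.
#' @return A [pheromone_field()] at time `until`.
#' @export
field_from_trajectories <- function(traj, cell_size = 1, extent = NULL,
                                    half_life = Inf, footprint_radius = 1,
                                    frame_rate = 25, until = NULL) {
  check_trajectories(traj)
  if (is.null(extent)) extent <- auto_extent(traj, cell_size)
  if (is.null(until)) until <- max(traj$t_s)
  st <- deposit_stream(traj, cell_size, extent$origin, extent$dim_rc,
                       footprint_radius, frame_rate)
  keep <- st$t <= until + 1e-9
  g <- numeric(prod(extent$dim_rc))
  if (any(keep)) {
    amp <- if (is.finite(half_life)) 2^(st$t[keep] / half_life) else 1
    agg <- rowsum(st$dq[keep] * amp, st$cell[keep])
    g[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    if (is.finite(half_life)) g <- g * 2^(-until / half_life)
  }
  pheromone_field(matrix(g, extent$dim_rc[1], extent$dim_rc[2]),
                  cell_size = cell_size, origin = extent$origin,
                  time = until, half_life = half_life)
}

#' Lazily replayable field history
#'
#' Stores the deduplicated deposit stream of a trajectory set so the field
#' state at any past time can be reproduced exactly (deposits up to t, then
#' closed-form evaporation). Used by [annotate_concentrations()] and
#' [correlation_map()] to query the field as it was `lag` seconds before
#' each tracking event.
#'
#' @inheritParams field_from_trajectories
#' @return An object of class `field_replayer`.
#' @export
field_replayer <- function(traj, cell_size = 1, extent = NULL,
                           half_life = Inf, footprint_radius = 1,
                           frame_rate = 25) {
  check_trajectories(traj)
  if (is.null(extent)) extent <- auto_extent(traj, cell_size)
  st <- deposit_stream(traj, cell_size, extent$origin, extent$dim_rc,
                       footprint_radius, frame_rate)
  structure(list(stream = st, cell_size = cell_size, origin = extent$origin,
                 dim_rc = extent$dim_rc, half_life = half_life),
            class = "field_replayer")
}

#' @export
print.field_replayer <- function(x, ...) {
  cat(sprintf(
    "<field_replayer> %d x %d cells, %d deposit increments, half-life %s\n",
    x$dim_rc[1], x$dim_rc[2], length(x$stream$t),
    if (is.finite(x$half_life)) paste0(x$half_life, " s") else "Inf"))
  invisible(x)
}

#' Reconstruct the field at a given time from a replayer
#'
#' @param replayer a [field_replayer()].
#' @param t time in seconds.
#' @return A [pheromone_field()] at time `t`.
#' @export
field_at <- function(replayer, t) {
  stopifnot(inherits(replayer, "field_replayer"))
  st <- replayer$stream
  keep <- st$t <= t + 1e-9
  g <- numeric(prod(replayer$dim_rc))
  if (any(keep)) {
    hl <- replayer$half_life
    amp <- if (is.finite(hl)) 2^(st$t[keep] / hl) else 1
    agg <- rowsum(st$dq[keep] * amp, st$cell[keep])
    g[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    if (is.finite(hl)) g <- g * 2^(-t / hl)
  }
  pheromone_field(matrix(g, replayer$dim_rc[1], replayer$dim_rc[2]),
                  cell_size = replayer$cell_size, origin = replayer$origin,
                  time = t, half_life = replayer$half_life)
}

# ---------------------------------------------------------------------------
# Field files: JSON sidecar + row-major little-endian float32 payload, plus
# a plain CSV grid for small fixtures.
# ---------------------------------------------------------------------------

#' Write / read a pheromone field
#'
#' `write_field()` stores the grid as a little-endian float32 binary payload
#' (`<path>.bin`, row-major) with a JSON sidecar (`<path>.json`) holding the
#' geometry and timestamp; `read_field()` reverses it. `write_field_csv()` /
#' `read_field_csv()` use a plain CSV grid for small diffable fixtures.
#'
#' @param field a [pheromone_field()].
#' @param path file path without extension (binary pair) or a `.csv` path.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "pheromone_field"))
  meta <- list(cell_size_mm = field$cell_size, origin = field$origin,
               time_s = field$time,
               half_life_s = if (is.finite(field$half_life))
                 field$half_life else "Inf",
               shape = dim(field$grid), dtype = "float32",
               order = "row-major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(field$grid)), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = prod(shape), size = 4, endian = "little")
  hl <- if (identical(meta$half_life_s, "Inf")) Inf else
    as.numeric(meta$half_life_s)
  pheromone_field(t(matrix(v, shape[2], shape[1])),
                  cell_size = meta$cell_size_mm,
                  origin = as.numeric(meta$origin), time = meta$time_s,
                  half_life = hl)
}

#' @rdname write_field
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "pheromone_field"))
  utils::write.table(field$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @param ... geometry arguments passed to [pheromone_field()].
#' @export
read_field_csv <- function(path, ...) {
  g <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(g) <- NULL
  pheromone_field(g, ...)
}

#' Spatial Gini coefficient of a field
#'
#' Inequality of the pheromone distribution over cells: 0 for a uniform
#' field, approaching 1 when all pheromone sits on a vanishing fraction of
#' cells. Used as a scalar summary of trail concentration.
#'
#' @param x a [pheromone_field()] or a numeric matrix/vector.
#' @export
spatial_gini <- function(x) {
  v <- if (inherits(x, "pheromone_field")) as.numeric(x$grid) else
    as.numeric(x)
  v <- sort(v)
  n <- length(v)
  if (sum(v) == 0) return(0)
  2 * sum(seq_len(n) * v) / (n * sum(v)) - (n + 1) / n
}
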