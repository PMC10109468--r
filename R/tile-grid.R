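#' Tiled SEM montage acquisition geometry
#'
#' A `tile_grid` describes one automated SEM montage: a regular grid of
#' partially overlapping image tiles acquired over a contiguous rock surface.
#' The horizontal field of view and the pixel dimensions fix the pixel pitch
#' (square pixels assumed), from which the tile height follows; the overlap
#' fraction is applied identically on both axes as a fraction of the tile
#' extent on that axis.
#'
#' The montage coordinate frame has its origin at the top-left corner of the
#' top-left tile, x increasing rightward and y downward, in micrometres.
#' Tile indices are 0-based and tile footprints are closed intervals, so a
#' point on a shared boundary belongs to both tiles.
#'
#' @param n_cols,n_rows Number of tile columns/rows (integers >= 1).
#' @param tile_px_x,tile_px_y Tile dimensions in pixels (integers >= 1).
#' @param fov_width_um Horizontal field of view of one tile, micrometres (> 0).
#' @param overlap_frac Fractional overlap between neighbouring tiles per axis,
#'   in `[0, 1)`.
#' @param dwell_s_per_image Acquisition time per tile, seconds (>= 0).
#'
#' @return An object of class `tile_grid`.
#' @examples
#' g <- tile_grid(60, 60, 6144, 4090, fov_width_um = 120,
#'                overlap_frac = 0.125, dwell_s_per_image = 8)
#' tile_footprint(g)
#' montage_extent(g)
#' @export
tile_grid <- function(n_cols, n_rows, tile_px_x, tile_px_y, fov_width_um,
                      overlap_frac = 0.125, dwell_s_per_image = 0) {
  for (nm in c("n_cols", "n_rows", "tile_px_x", "tile_px_y")) {
    v <- get(nm)
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v < 1 ||
        v != as.integer(v)) {
      stop(sprintf("`%s` must be a single integer >= 1", nm), call. = FALSE)
    }
  }
  if (!is.numeric(fov_width_um) || length(fov_width_um) != 1L ||
      !is.finite(fov_width_um) || fov_width_um <= 0) {
    stop("`fov_width_um` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(overlap_frac) || length(overlap_frac) != 1L ||
      is.na(overlap_frac) || overlap_frac < 0 || overlap_frac >= 1) {
    stop("`overlap_frac` must be in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(dwell_s_per_image) || length(dwell_s_per_image) != 1L ||
      is.na(dwell_s_per_image) || dwell_s_per_image < 0) {
    stop("`dwell_s_per_image` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
      tile_px_x = as.integer(tile_px_x), tile_px_y = as.integer(tile_px_y),
      fov_width_um = as.numeric(fov_width_um),
      overlap_frac = as.numeric(overlap_frac),
      dwell_s_per_image = as.numeric(dwell_s_per_image)
    ),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  fp <- tile_footprint(x)
  ext <- montage_extent(x)
  cat(sprintf(
    paste0(
      "<tile_grid> %d x %d tiles (%d images)\n",
      "  tile: %d x %d px, %.6g x %.6g um, pixel pitch %.4g nm\n",
      "  overlap: %.3g per axis; dwell: %g s/image\n",
      "  montage: %.1f x %.1f mm (reported area %.3f cm^2)\n"
    ),
    x$n_cols, x$n_rows, x$n_cols * x$n_rows,
    x$tile_px_x, x$tile_px_y, fp$width_um, fp$height_um, fp$pixel_pitch_nm,
    x$overlap_frac, x$dwell_s_per_image,
    ext$width_mm, ext$height_mm, ext$area_cm2
  ))
  invisible(x)
}

is_tile_grid <- function(x) inherits(x, "tile_grid")

assert_tile_grid <- function(grid) {
  if (!is_tile_grid(grid)) stop("`grid` must be a `tile_grid`", call. = FALSE)
  invisible(grid)
}

# tile extent (um) per axis; height derives from the pixel pitch
tile_extent_um <- function(grid) {
  pitch <- grid$fov_width_um / grid$tile_px_x
  c(x = grid$fov_width_um, y = grid$tile_px_y * pitch)
}

# stage step between neighbouring tile origins (um) per axis
tile_step_um <- function(grid) {
  tile_extent_um(grid) * (1 - grid$overlap_frac)
}

#' Tile footprint and pixel pitch
#'
#' @param grid A [tile_grid()].
#' @return A list with `width_um`, `height_um` (physical tile extent) and
#'   `pixel_pitch_nm`. Width equals the stated field of view; height is
#'   derived from the pixel aspect ratio assuming square pixels.
#' @examples
#' tile_footprint(tile_grid(1, 1, 6144, 4090, 120))
#' @export
tile_footprint <- function(grid) {
  assert_tile_grid(grid)
  ext <- tile_extent_um(grid)
  list(
    width_um = unname(ext["x"]),
    height_um = unname(ext["y"]),
    pixel_pitch_nm = 1000 * grid$fov_width_um / grid$tile_px_x
  )
}

#' Montage extent and imaged area
#'
#' The montage extent per axis is `tile_extent * (1 + (n - 1) * (1 -
#' overlap_frac))`: overlapping strips are counted once. Reported values
#' follow the survey's reporting convention — extents rounded to 0.1 mm, the
#' area formed as the product of the rounded extents and rounded to three
#' decimals of a square centimetre — while exact (unrounded) values are
#' returned alongside.
#'
#' @param grid A [tile_grid()].
#' @return A list: `width_mm`, `height_mm`, `area_cm2` (reported values) and
#'   `width_um_exact`, `height_um_exact`, `area_cm2_exact`.
#' @examples
#' montage_extent(tile_grid(60, 60, 6144, 4090, 120, 0.125))
#' @export
montage_extent <- function(grid) {
  assert_tile_grid(grid)
  ext <- tile_extent_um(grid)
  n <- c(x = grid$n_cols, y = grid$n_rows)
  span_um <- ext * (1 + (n - 1) * (1 - grid$overlap_frac))
  width_mm <- round(span_um[["x"]] / 1000, 1)
  height_mm <- round(span_um[["y"]] / 1000, 1)
  list(
    width_mm = width_mm,
    height_mm = height_mm,
    area_cm2 = round(width_mm * height_mm / 100, 3),
    width_um_exact = span_um[["x"]],
    height_um_exact = span_um[["y"]],
    area_cm2_exact = span_um[["x"]] * span_um[["y"]] / 1e8
  )
}

assert_tile_index <- function(grid, col, row) {
  if (any(col < 0L | col >= grid$n_cols | row < 0L | row >= grid$n_rows |
          col != floor(col) | row != floor(row))) {
    stop(sprintf("tile index out of grid (%d x %d)",
                 grid$n_cols, grid$n_rows), call. = FALSE)
  }
}

#' Convert tile-local to montage-global coordinates (and back)
#'
#' Tile origins sit on a regular lattice with step `tile_extent * (1 -
#' overlap_frac)` per axis, so a global position is the tile origin plus the
#' tile-local offset. Both functions are vectorised over points and tile
#' indices.
#'
#' @param grid A [tile_grid()].
#' @param col,row 0-based tile indices.
#' @param x_um,y_um Coordinates in micrometres: tile-local for
#'   `local_to_global()`, montage-global for `global_to_tile_local()`.
#' @return A [tibble::tibble()] with columns `x_um`, `y_um`.
#' @examples
#' g <- tile_grid(2, 1, 1000, 1000, 120, 0.125)
#' local_to_global(g, 1, 0, 0, 0)  # x = 0.875 * 120
#' @export
local_to_global <- function(grid, col, row, x_um, y_um) {
  assert_tile_grid(grid)
  assert_tile_index(grid, col, row)
  step <- tile_step_um(grid)
  tibble::tibble(
    x_um = col * step[["x"]] + x_um,
    y_um = row * step[["y"]] + y_um
  )
}

#' @rdname local_to_global
#' @export
global_to_tile_local <- function(grid, col, row, x_um, y_um) {
  assert_tile_grid(grid)
  assert_tile_index(grid, col, row)
  step <- tile_step_um(grid)
  tibble::tibble(
    x_um = x_um - col * step[["x"]],
    y_um = y_um - row * step[["y"]]
  )
}

# index range of tiles whose closed footprint contains coordinate v on one
# axis; a small relative tolerance guards boundary floating point
axis_tiles <- function(v, extent, step, n, tol = 1e-9) {
  if (step == 0) { # full overlap is excluded by the type, defensive only
    return(if (v >= -tol && v <= extent + tol) 0:(n - 1L) else integer(0))
  }
  lo <- max(0L, as.integer(ceiling((v - extent) / step - tol)))
  hi <- min(n - 1L, as.integer(floor(v / step + tol)))
  if (lo > hi) integer(0) else lo:hi
}

#' Tiles whose footprint contains a point
#'
#' Returns every tile whose (closed) footprint contains the montage-global
#' point on both axes: one tile for a point in a tile's non-overlap core, two
#' for a one-axis overlap strip, four for a corner overlap. A point outside
#' the montage extent yields zero rows.
#'
#' @param grid A [tile_grid()].
#' @param x_um,y_um A single montage-global point, micrometres.
#' @return A [tibble::tibble()] with columns `col`, `row` (0-based).
#' @examples
#' g <- tile_grid(2, 2, 1000, 1000, 120, 0.125)
#' tiles_covering(g, 110, 30)  # in the vertical overlap strip: two tiles
#' @export
tiles_covering <- function(grid, x_um, y_um) {
  assert_tile_grid(grid)
  stopifnot(length(x_um) == 1L, length(y_um) == 1L)
  ext <- tile_extent_um(grid)
  step <- tile_step_um(grid)
  cols <- axis_tiles(x_um, ext[["x"]], step[["x"]], grid$n_cols)
  rows <- axis_tiles(y_um, ext[["y"]], step[["y"]], grid$n_rows)
  if (length(cols) == 0L || length(rows) == 0L) {
    return(tibble::tibble(col = integer(0), row = integer(0)))
  }
  grd <- expand.grid(col = cols, row = rows)
  tibble::tibble(col = as.integer(grd$col), row = as.integer(grd$row))
}

#' Whole-dataset acquisition totals
#'
#' @param grids A list of [tile_grid()] objects, one per montage (a single
#'   `tile_grid` is accepted).
#' @return A list: `n_images`, `total_area_cm2` (sum of the per-montage
#'   rounded-extent areas, rounded to 2 decimals), `total_area_cm2_exact`,
#'   `acquisition_hours` (per montage) and `acquisition_hours_total`.
#' @examples
#' g <- tile_grid(60, 60, 6144, 4090, 120, 0.125, dwell_s_per_image = 8)
#' dataset_totals(rep(list(g), 7))
#' @export
dataset_totals <- function(grids) {
  if (is_tile_grid(grids)) grids <- list(grids)
  if (!is.list(grids) || length(grids) == 0L ||
      !all(vapply(grids, is_tile_grid, logical(1)))) {
    stop("`grids` must be a non-empty list of `tile_grid` objects",
         call. = FALSE)
  }
  exts <- lapply(grids, montage_extent)
  n_images <- sum(vapply(grids, function(g) g$n_cols * g$n_rows, numeric(1)))
  per_area <- vapply(exts, function(e) e$width_mm * e$height_mm / 100,
                     numeric(1))
  hours <- vapply(grids, function(g) {
    g$n_cols * g$n_rows * g$dwell_s_per_image / 3600
  }, numeric(1))
  list(
    n_images = as.integer(n_images),
    total_area_cm2 = round(sum(per_area), 2),
    total_area_cm2_exact = sum(vapply(exts, `[[`, numeric(1),
                                      "area_cm2_exact")),
    acquisition_hours = hours,
    acquisition_hours_total = sum(hours)
  )
}

#' Canonical image identifier for a tile
#'
#' @param montage Montage identifier (character).
#' @param col,row 0-based tile indices.
#' @return Character vector of image ids, e.g. `"m1_c004_r017"`.
#' @export
image_id <- function(montage, col, row) {
  sprintf("%s_c%03d_r%03d", montage, as.integer(col), as.integer(row))
}

# all image ids of a montage, row-major
all_image_ids <- function(grid, montage) {
  grd <- expand.grid(col = 0:(grid$n_cols - 1L), row = 0:(grid$n_rows - 1L))
  image_id(montage, grd$col, grd$row)
}
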