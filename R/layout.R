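#' Mosaic layout of a tile scan
#'
#' Describes the grid of square tiles making up a whole-section scan: grid
#' dimensions, tile side in pixels, the width of the border strip excluded
#' from analysis on each tile side, and the physical pixel size. Tiles are
#' assumed to abut edge to edge; the border exclusion compensates for
#' acquisition overlap between neighbouring tiles, so each cell is counted
#' in exactly one tile.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param side_px Tile side in pixels.
#' @param border_px Width of the excluded strip on each side of a tile, in
#'   pixels; must satisfy `2 * border_px < side_px`.
#' @param pixel_size_um Physical pixel size in micrometres (> 0).
#' @return A `mosaic_layout` object.
#' @examples
#' mosaic_layout(2, 3, side_px = 512, border_px = 48, pixel_size_um = 0.5)
#' @export
mosaic_layout <- function(n_rows, n_cols, side_px, border_px = 0L,
                          pixel_size_um = 0.5) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  side_px <- as.integer(side_px); border_px <- as.integer(border_px)
  if (n_rows < 1 || n_cols < 1) abort("n_rows and n_cols must be >= 1")
  if (!(border_px >= 0 && 2L * border_px < side_px)) {
    abort("border_px must satisfy 0 <= 2*border_px < side_px")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    abort("pixel_size_um must be > 0")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, side_px = side_px,
         border_px = border_px, pixel_size_um = pixel_size_um),
    class = "mosaic_layout"
  )
}

#' @export
print.mosaic_layout <- function(x, ...) {
  cat(sprintf(
    "<mosaic_layout> %d x %d tiles, side %d px, border %d px, %.4g um/px\n",
    x$n_rows, x$n_cols, x$side_px, x$border_px, x$pixel_size_um))
  invisible(x)
}

#' Per-tile analysis mask with border exclusion
#'
#' Tile scans of adjacent fields overlap slightly at their edges; to avoid
#' counting the same cell twice, a fixed-width strip on each side of every
#' tile is omitted from analysis. The mask is true exactly on the centred
#' `(side - 2*border)^2` square. The excluded fraction is the exact pixel
#' ratio `1 - ((side - 2*border)/side)^2`; note the often-quoted strip
#' arithmetic `4*border*side / side^2` double-counts the four corners, though
#' both round to the same percentage at typical settings (9% for a 2048 px
#' tile with a 48 px border).
#'
#' @param layout A [mosaic_layout()].
#' @return A list with `mask` (logical `side_px` x `side_px` matrix, indexed
#'   `[y + 1, x + 1]`) and `excluded_fraction`.
#' @examples
#' m <- analysis_mask(mosaic_layout(1, 1, 2048, 48, 0.5))
#' round(m$excluded_fraction, 2)  # 0.09
#' @export
analysis_mask <- function(layout) {
  stopifnot(inherits(layout, "mosaic_layout"))
  s <- layout$side_px; b <- layout$border_px
  mask <- matrix(FALSE, s, s)
  mask[(b + 1):(s - b), (b + 1):(s - b)] <- TRUE
  list(mask = mask, excluded_fraction = 1 - ((s - 2 * b) / s)^2)
}

#' Map tile-local pixel coordinates to global micrometre coordinates
#'
#' Pixel `(x, y)` of the tile at grid position `(row, col)` maps to
#' `((col*side + x) * pixel_size, (row*side + y) * pixel_size)` micrometres,
#' with 0-based pixels, x along columns and y along rows, origin at the
#' top-left of tile (0, 0). The mapping is exactly invertible via
#' [to_local()].
#'
#' @param points A two-column matrix or data frame of (x, y) pixel
#'   coordinates within the tile.
#' @param grid_pos Integer pair `(row, col)`, 0-based.
#' @param layout A [mosaic_layout()].
#' @return A tibble with columns `x_um`, `y_um`.
#' @export
to_global <- function(points, grid_pos, layout) {
  stopifnot(inherits(layout, "mosaic_layout"))
  points <- as.matrix(points)
  if (!nrow(points)) return(tibble(x_um = double(), y_um = double()))
  s <- layout$side_px
  if (any(points[, 1] < 0 | points[, 1] > s - 1 |
          points[, 2] < 0 | points[, 2] > s - 1)) {
    abort("point outside tile bounds")
  }
  row <- as.integer(grid_pos[1]); col <- as.integer(grid_pos[2])
  if (row < 0 || row >= layout$n_rows || col < 0 || col >= layout$n_cols) {
    abort("grid_pos outside layout")
  }
  tibble(
    x_um = (col * s + points[, 1]) * layout$pixel_size_um,
    y_um = (row * s + points[, 2]) * layout$pixel_size_um
  )
}

#' @rdname to_global
#' @param points_um A two-column matrix/data frame of global (x_um, y_um).
#' @return `to_local()`: a list with `points` (tibble `x`, `y` in px) and
#'   `grid_pos`.
#' @export
to_local <- function(points_um, layout) {
  stopifnot(inherits(layout, "mosaic_layout"))
  p <- as.matrix(points_um)
  px <- p[, 1] / layout$pixel_size_um
  py <- p[, 2] / layout$pixel_size_um
  col <- pmin(floor(px / layout$side_px), layout$n_cols - 1)
  row <- pmin(floor(py / layout$side_px), layout$n_rows - 1)
  list(points = tibble(x = px - col * layout$side_px,
                       y = py - row * layout$side_px),
       grid_pos = cbind(row = row, col = col))
}

#' @rdname mosaic_layout
#' @param path Path to a YAML file with fields `n_rows`, `n_cols`, `side_px`,
#'   `border_px`, `pixel_size_um`.
#' @export
read_layout <- function(path) {
  y <- yaml::read_yaml(path)
  mosaic_layout(y$n_rows, y$n_cols, y$side_px, y$border_px %||% 0L,
                y$pixel_size_um %||% 0.5)
}

#' @rdname mosaic_layout
#' @param layout A `mosaic_layout` to serialise.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "mosaic_layout"))
  yaml::write_yaml(unclass(layout), path)
  invisible(path)
}
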