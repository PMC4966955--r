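#' Partition a grid into rectangular tiles
#'
#' The tiled (hierarchical) EOF strategy keeps the decomposed matrices
#' small on large grids: the grid is divided into disjoint rectangular
#' tiles of nominal size \code{tile_rows x tile_cols} (default 200 x 200
#' pixels, a 200 km x 200 km region at 1 km pixel size) and any
#' field-to-field operation is applied tile by tile. Edge tiles may be
#' smaller; a tile larger than the grid clamps to a single tile. Tiles
#' are disjoint and jointly cover the grid exactly once. There is no
#' overlap or seam blending.
#'
#' @param grid_shape integer \code{c(rows, cols)} of the full grid.
#' @param tile_rows,tile_cols nominal tile size in pixels (each >= 2).
#' @return an object of class \code{"tile_layout"}: list with
#'   \code{grid_shape}, \code{tile_rows}, \code{tile_cols} and
#'   \code{tiles}, a list of \code{(r0, r1, c0, c1)} pixel ranges.
#' @export
make_layout <- function(grid_shape, tile_rows = 200L, tile_cols = 200L) {
  grid_shape <- as.integer(grid_shape)
  tile_rows <- as.integer(tile_rows); tile_cols <- as.integer(tile_cols)
  if (tile_rows < 2L || tile_cols < 2L)
    stop("parameter error: tile dimensions must be >= 2 pixels")
  tile_rows <- min(tile_rows, grid_shape[1])
  tile_cols <- min(tile_cols, grid_shape[2])
  r_starts <- seq(1L, grid_shape[1], by = tile_rows)
  c_starts <- seq(1L, grid_shape[2], by = tile_cols)
  tiles <- list()
  for (r0 in r_starts) for (c0 in c_starts)
    tiles[[length(tiles) + 1L]] <- c(
      r0 = r0, r1 = min(r0 + tile_rows - 1L, grid_shape[1]),
      c0 = c0, c1 = min(c0 + tile_cols - 1L, grid_shape[2]))
  structure(list(grid_shape = grid_shape, tile_rows = tile_rows,
                 tile_cols = tile_cols, tiles = tiles),
            class = "tile_layout")
}

#' @export
print.tile_layout <- function(x, ...) {
  cat(sprintf("<tile_layout> %d tile(s) of nominal %dx%d on a %dx%d grid\n",
              length(x$tiles), x$tile_rows, x$tile_cols,
              x$grid_shape[1], x$grid_shape[2]))
  invisible(x)
}

## Extract the sub-field of one tile, preserving times and pixel size.
extract_tile <- function(field, tile) {
  rows <- tile["r0"]:tile["r1"]; cols <- tile["c0"]:tile["c1"]
  idx <- pixel_rows(field$grid_shape, rows, cols)
  space_time_field(field$values[idx, , drop = FALSE],
                   grid_shape = c(length(rows), length(cols)),
                   mask = field$mask[idx, , drop = FALSE],
                   times = field$times, pixel_size = field$pixel_size)
}

#' Apply a field-to-field operation tile by tile and stitch the results
#'
#' @param field a \code{\link{space_time_field}}.
#' @param layout a \code{\link{make_layout}} result matching the field's
#'   grid.
#' @param op a function taking (and returning) a
#'   \code{\link{space_time_field}} with unchanged grid shape and time
#'   axis.
#' @param ... passed on to \code{op}.
#' @return the stitched \code{\link{space_time_field}}.
#' @export
map_tiles <- function(field, layout, op, ...) {
  stopifnot(inherits(field, "space_time_field"), inherits(layout, "tile_layout"))
  if (!identical(layout$grid_shape, field$grid_shape))
    stop("layout grid does not match the field grid")
  out_vals <- field$values
  out_mask <- field$mask
  for (t in seq_along(layout$tiles)) {
    tile <- layout$tiles[[t]]
    sub <- extract_tile(field, tile)
    res <- op(sub, ...)
    if (!inherits(res, "space_time_field") ||
        !identical(dim(res$values), dim(sub$values)))
      stop(sprintf("contract error: op returned the wrong shape for tile %d", t))
    idx <- pixel_rows(field$grid_shape, tile["r0"]:tile["r1"],
                      tile["c0"]:tile["c1"])
    out_vals[idx, ] <- res$values
    out_mask[idx, ] <- res$mask
  }
  space_time_field(out_vals, grid_shape = field$grid_shape, mask = out_mask,
                   times = field$times, pixel_size = field$pixel_size)
}
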