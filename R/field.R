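#' Space-time field of latent heat flux
#'
#' The package's central container: a gridded LE stack flattened to a
#' \code{P x N} matrix (P spatial pixels as rows, N time steps as columns)
#' together with an explicit missing-data mask. The grid is unravelled
#' row-major from the north-west corner, so pixel \code{(r, c)} on an
#' \code{nr x nc} grid sits in matrix row \code{(r - 1) * nc + c}.
#'
#' Missingness is encoded by the logical \code{mask} (\code{TRUE} =
#' missing), not by \code{NA} alone: downstream algorithms must consult the
#' mask only, so the values stored under masked cells are irrelevant (and
#' may legitimately be \code{NA} or arbitrary sentinels). Values at
#' non-masked cells must be finite.
#'
#' The time axis must be strictly increasing and regularly spaced (daily or
#' 8-day composites); the delay embedding assumes uniform sampling.
#'
#' @param values numeric \code{P x N} matrix of LE in W/m2.
#' @param grid_shape integer vector \code{c(rows, cols)} with
#'   \code{rows * cols == nrow(values)}.
#' @param mask logical matrix of the same shape, \code{TRUE} where the
#'   observation is missing. Defaults to \code{is.na(values)}.
#' @param times numeric or \code{Date} vector of length \code{N}, strictly
#'   increasing, regularly spaced. Defaults to \code{1:N}.
#' @param pixel_size pixel edge length in metres (default 1000, i.e. 1 km).
#'
#' @return An object of class \code{"space_time_field"}.
#' @examples
#' f <- space_time_field(matrix(1:12, 4, 3), grid_shape = c(2, 2))
#' dim(f)
#' @export
space_time_field <- function(values, grid_shape, mask = NULL, times = NULL,
                             pixel_size = 1000) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (pixels x time)")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop("`grid_shape` must be two positive integers c(rows, cols)")
  if (prod(grid_shape) != nrow(values))
    stop(sprintf("grid_shape %dx%d does not match %d pixel rows",
                 grid_shape[1], grid_shape[2], nrow(values)))
  if (is.null(mask)) mask <- is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    stop("`mask` must be a logical matrix with the same shape as `values`")
  if (is.null(times)) times <- seq_len(ncol(values))
  if (length(times) != ncol(values))
    stop("`times` length must equal the number of time steps")
  dt <- diff(as.numeric(times))
  if (length(dt) > 0L) {
    if (any(dt <= 0)) stop("time axis must be strictly increasing")
    if (length(dt) > 1L && any(abs(dt - dt[1]) > 1e-6 * abs(dt[1])))
      stop("time axis must be regularly spaced")
  }
  if (any(!is.finite(values[!mask])))
    stop("non-masked values must all be finite")
  structure(
    list(values = values, mask = mask, grid_shape = grid_shape,
         times = times, pixel_size = pixel_size),
    class = "space_time_field")
}

#' @export
dim.space_time_field <- function(x) dim(x$values)

#' @export
as.matrix.space_time_field <- function(x, ...) x$values

#' @export
print.space_time_field <- function(x, ...) {
  obs <- x$values[!x$mask]
  cat(sprintf("<space_time_field> %d x %d grid, %d time steps\n",
              x$grid_shape[1], x$grid_shape[2], ncol(x$values)))
  cat(sprintf("  missing: %.1f%%   LE range (observed): [%.2f, %.2f] W/m2\n",
              100 * mean(x$mask),
              if (length(obs)) min(obs) else NA, if (length(obs)) max(obs) else NA))
  invisible(x)
}

## Replace the value matrix, keeping geometry; mask defaults to all-observed.
field_with_values <- function(field, values, mask = NULL) {
  if (is.null(mask))
    mask <- matrix(FALSE, nrow(values), ncol(values))
  space_time_field(values, grid_shape = field$grid_shape, mask = mask,
                   times = field$times, pixel_size = field$pixel_size)
}

## Matrix row indices of the pixels in grid rows `rows` x grid cols `cols`.
pixel_rows <- function(grid_shape, rows, cols) {
  as.vector(t(outer((rows - 1L) * grid_shape[2], cols, `+`)))
}

stopifnot_coregistered <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      !identical(a$grid_shape, b$grid_shape))
    stop("products are not co-registered: grids differ")
  if (!isTRUE(all.equal(as.numeric(a$times), as.numeric(b$times))))
    stop("products are not co-registered: time axes differ")
  invisible(TRUE)
}
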