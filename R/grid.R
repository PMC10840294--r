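#' Raster grid geometry
#'
#' A `raster_grid` describes the shared geometry of every raster in a pipeline
#' run: shape, georeferencing (top-left origin, square pixels) and CRS label.
#' All layers are stored as base matrices (`nrow x ncol`, row 1 = northern
#' edge); `NA` is the in-memory nodata value.
#'
#' @param nrow,ncol raster shape in pixels.
#' @param xmin,ymax coordinates of the top-left (north-west) grid corner.
#' @param px pixel size in metres (square pixels; default 10 m, so one pixel
#'   covers 100 m2).
#' @param crs coordinate reference system label (free-form string; the package
#'   never reprojects, it only checks that grids match).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(nrow, ncol, xmin = 0, ymax = nrow * px, px = 10,
                        crs = "local") {
  stopifnot(nrow >= 1, ncol >= 1, px > 0)
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         xmin = xmin, ymax = ymax, px = px, crs = crs),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d px, pixel %g m, origin (%g, %g), crs '%s'\n",
              x$nrow, x$ncol, x$px, x$xmin, x$ymax, x$crs))
  invisible(x)
}

#' @rdname raster_grid
#' @param a,b two `raster_grid` objects.
#' @export
grids_equal <- function(a, b) {
  isTRUE(a$nrow == b$nrow && a$ncol == b$ncol &&
         abs(a$xmin - b$xmin) < 1e-9 && abs(a$ymax - b$ymax) < 1e-9 &&
         abs(a$px - b$px) < 1e-12 && identical(a$crs, b$crs))
}

grid_extent <- function(grid) {
  c(xmin = grid$xmin, xmax = grid$xmin + grid$ncol * grid$px,
    ymin = grid$ymax - grid$nrow * grid$px, ymax = grid$ymax)
}

#' Map point coordinates to pixel row/column
#'
#' Containment is half-open in pixel footprints: a point lying exactly on a
#' pixel's western or northern edge belongs to that pixel, so sampling is
#' deterministic on boundaries.
#'
#' @param grid a [raster_grid()].
#' @param x,y point coordinates (same CRS/units as the grid).
#' @return Integer matrix with columns `row`, `col`; `NA` rows for points
#'   outside the grid extent.
#' @export
xy_to_rowcol <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$px) + 1L
  row <- floor((grid$ymax - y) / grid$px) + 1L
  ok <- col >= 1L & col <= grid$ncol & row >= 1L & row <= grid$nrow
  col[!ok] <- NA_integer_
  row[!ok] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' @rdname xy_to_rowcol
#' @param row,col pixel indices (1-based).
#' @return For `rowcol_to_xy`: matrix of pixel-centre coordinates.
#' @export
rowcol_to_xy <- function(grid, row, col) {
  cbind(x = grid$xmin + (col - 0.5) * grid$px,
        y = grid$ymax - (row - 0.5) * grid$px)
}

# assert that `grid` matches `ref`, naming the offender in the error
check_grid <- function(grid, ref, what = "raster") {
  if (!grids_equal(grid, ref)) {
    stop("alignment error: ", what,
         " is not on the pipeline grid (no implicit resampling is performed)",
         call. = FALSE)
  }
  invisible(TRUE)
}

# assert a layer has the grid's shape
check_layer <- function(values, grid, what = "layer") {
  if (!is.matrix(values) || nrow(values) != grid$nrow || ncol(values) != grid$ncol) {
    stop("alignment error: ", what, " shape does not match the grid", call. = FALSE)
  }
  invisible(TRUE)
}
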