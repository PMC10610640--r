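#' Georeferenced raster grid
#'
#' A minimal single-layer raster: a numeric matrix plus a north-up affine
#' georeference in a projected (metric) CRS. Cells are row-major with the
#' origin at the top-left corner; cell `(1, 1)` covers the half-open box
#' `[xmin, xmin + dx) x (ymax - dy, ymax]`, so every planar point maps to at
#' most one cell. Missing cells are stored as `NA` and are excluded from every
#' statistic; the `nodata` sentinel is only materialised on disk.
#'
#' @param values Numeric matrix (rows = north to south, columns = west to
#'   east). `NA` marks no-data cells.
#' @param xmin,ymax Projected coordinates (metres) of the grid's top-left
#'   corner.
#' @param dx,dy Cell width and height in metres; both strictly positive.
#' @param crs Character label of the projected CRS, e.g.
#'   `"ETRS89 / UTM zone 29N"`. Required: rasters without georeferencing are
#'   rejected on read.
#' @param nodata Sentinel value used when the grid is written to GeoTIFF.
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:6, 2, 3), xmin = 0, ymax = 2, dx = 1, dy = 1,
#'                  crs = "local metric")
#' raster_res(g)
#' @export
raster_grid <- function(values, xmin, ymax, dx, dy, crs, nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(dx) || !is.numeric(dy) || dx <= 0 || dy <= 0)
    stop("cell sizes dx and dy must be strictly positive")
  if (!is.character(crs) || length(crs) != 1L || !nzchar(crs))
    stop("a non-empty CRS label is required")
  if (any(is.infinite(values)))
    stop("raster values must be finite or NA")
  structure(
    list(values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         dx = as.numeric(dx), dy = as.numeric(dy), crs = crs,
         nodata = as.numeric(nodata)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<raster_grid> %d x %d cells, %.3g x %.3g m/cell, CRS '%s'\n",
              nrow(x$values), ncol(x$values), x$dx, x$dy, x$crs))
  cat(sprintf("  extent x [%.3f, %.3f] y [%.3f, %.3f]; %d no-data cells\n",
              x$xmin, x$xmin + ncol(x$values) * x$dx,
              x$ymax - nrow(x$values) * x$dy, x$ymax,
              sum(!is.finite(x$values))))
  if (length(v))
    cat(sprintf("  values: min %.4g  mean %.4g  max %.4g\n",
                min(v), mean(v), max(v)))
  invisible(x)
}

#' @rdname raster_grid
#' @param x A `raster_grid`.
#' @export
raster_res <- function(x) c(dx = x$dx, dy = x$dy)

#' @rdname raster_grid
#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Coordinates of every cell center
#'
#' @param grid A [raster_grid()].
#' @return A list with matrices `x` and `y`, same shape as `grid$values`.
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  xs <- grid$xmin + (seq_len(nc) - 0.5) * grid$dx
  ys <- grid$ymax - (seq_len(nr) - 0.5) * grid$dy
  list(x = matrix(xs, nr, nc, byrow = TRUE), y = matrix(ys, nr, nc))
}

#' Map planar points to raster cells
#'
#' Uses the half-open cell convention `[x, x + dx) x (y - dy, y]`: a point on
#' a shared vertical edge belongs to the cell on its right, a point on a
#' shared horizontal edge to the cell above it, so each point lands in exactly
#' one cell. Points outside the grid get `NA`.
#'
#' @param grid A [raster_grid()].
#' @param x,y Numeric vectors of projected coordinates (metres).
#' @return Data frame with 1-based `row` and `col` (NA outside the grid).
#' @export
locate_cells <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$dx) + 1
  row <- ceiling((grid$ymax - y) / grid$dy)
  row[row == 0 & y == grid$ymax] <- 1
  bad <- col < 1 | col > ncol(grid$values) | row < 1 | row > nrow(grid$values)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

check_same_geometry <- function(a, b, what = "rasters") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("%s have different shapes (%s vs %s)", what,
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x")))
  tol <- 1e-9 * max(abs(c(a$dx, a$dy, 1)))
  if (abs(a$xmin - b$xmin) > tol || abs(a$ymax - b$ymax) > tol ||
      abs(a$dx - b$dx) > tol || abs(a$dy - b$dy) > tol)
    stop(sprintf("%s have different affine transforms", what))
  if (!identical(a$crs, b$crs))
    stop(sprintf("%s are in different CRS ('%s' vs '%s'); reprojection is not supported",
                 what, a$crs, b$crs))
  invisible(TRUE)
}
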