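#' Attributed 3D point cloud
#'
#' Points in a projected metric CRS with optional per-point attributes:
#' temperature (with an explicit unit -- never inferred from magnitude),
#' 8-bit RGB color, a classification label, and arbitrary named scalar fields
#' (e.g. `cwsi`). All attribute vectors must match the number of points, and
#' no operation in the package reorders points except the documented filters.
#'
#' @param coords Numeric N x 3 matrix of x, y, z in metres.
#' @param temperature Optional numeric vector of length N.
#' @param temp_unit `"celsius"` or `"kelvin"`; required when `temperature`
#'   is given.
#' @param color Optional N x 3 integer matrix with values in 0..255.
#' @param class_label Optional character/factor of length N with levels
#'   `ground`, `canopy`, `noise`, `unassigned`.
#' @param scalars Named list of additional numeric length-N vectors.
#' @param crs Character CRS label.
#' @return An object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(cbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)))
#' n_points(pc)
#' @export
point_cloud <- function(coords, temperature = NULL, temp_unit = NULL,
                        color = NULL, class_label = NULL, scalars = list(),
                        crs = "local metric") {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an N x 3 matrix")
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n > 0 && !all(is.finite(coords))) stop("coordinates must be finite")
  colnames(coords) <- c("x", "y", "z")

  if (!is.null(temperature)) {
    if (length(temperature) != n)
      stop("temperature length does not match the number of points")
    if (!all(is.finite(temperature)))
      stop("temperature must be finite where present")
    if (is.null(temp_unit) || !temp_unit %in% c("celsius", "kelvin"))
      stop("temp_unit must be declared as 'celsius' or 'kelvin'")
  }
  if (!is.null(color)) {
    color <- as.matrix(color)
    if (!identical(dim(color), c(n, 3L)) && !(n == 0 && ncol(color) == 3))
      stop("color must be an N x 3 matrix")
    storage.mode(color) <- "integer"
    if (n > 0 && (min(color) < 0 || max(color) > 255))
      stop("color values must lie in 0..255")
  }
  if (!is.null(class_label)) {
    class_label <- factor(as.character(class_label), levels = cloud_classes())
    if (length(class_label) != n)
      stop("class_label length does not match the number of points")
    if (n > 0 && anyNA(class_label))
      stop("class_label values must be one of ",
           paste(cloud_classes(), collapse = ", "))
  }
  if (length(scalars)) {
    if (is.null(names(scalars)) || any(!nzchar(names(scalars))))
      stop("scalar fields must be named")
    for (nm in names(scalars)) {
      if (length(scalars[[nm]]) != n)
        stop(sprintf("scalar field '%s' length does not match N", nm))
      scalars[[nm]] <- as.numeric(scalars[[nm]])
    }
  }
  structure(
    list(coords = coords, temperature = temperature,
         temp_unit = if (is.null(temperature)) NULL else temp_unit,
         color = color, class_label = class_label, scalars = scalars,
         crs = crs),
    class = "point_cloud")
}

cloud_classes <- function() c("ground", "canopy", "noise", "unassigned")

#' @rdname point_cloud
#' @param cloud A `point_cloud`.
#' @export
n_points <- function(cloud) nrow(cloud$coords)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, CRS '%s'\n", n_points(x), x$crs))
  if (!is.null(x$temperature))
    cat(sprintf("  temperature [%s]: %.2f .. %.2f\n", x$temp_unit,
                min(x$temperature), max(x$temperature)))
  if (!is.null(x$class_label))
    cat("  classes:", paste(sprintf("%s=%d", levels(x$class_label),
                                    tabulate(x$class_label, 4)),
                            collapse = " "), "\n")
  if (length(x$scalars))
    cat("  scalars:", paste(names(x$scalars), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a point cloud, keeping all attributes aligned
#'
#' @param cloud A [point_cloud()].
#' @param idx Logical or integer index over points; order is preserved.
#' @return A `point_cloud` with the selected points.
#' @export
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$coords[idx, , drop = FALSE],
              temperature = cloud$temperature[idx],
              temp_unit = cloud$temp_unit,
              color = if (!is.null(cloud$color)) cloud$color[idx, , drop = FALSE],
              class_label = if (!is.null(cloud$class_label)) cloud$class_label[idx],
              scalars = lapply(cloud$scalars, `[`, idx),
              crs = cloud$crs)
}

#' Attach or replace a scalar field
#'
#' @param cloud A [point_cloud()].
#' @param name Field name, e.g. `"cwsi"`.
#' @param values Numeric vector of length `n_points(cloud)`.
#' @export
set_scalar <- function(cloud, name, values) {
  if (length(values) != n_points(cloud))
    stop("scalar length does not match the number of points")
  cloud$scalars[[name]] <- as.numeric(values)
  cloud
}

#' Region-of-interest polygon
#'
#' An ordered planar ring (not repeated at the end) in a projected CRS. The
#' ring must be simple (no self-intersections) and enclose a positive area.
#'
#' @param vertices Numeric M x 2 matrix of x, y vertices in metres, M >= 3.
#' @param crs Character CRS label.
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices, crs = "local metric") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("ROI needs an M x 2 vertex matrix with M >= 3")
  storage.mode(vertices) <- "double"
  if (!all(is.finite(vertices))) stop("ROI vertices must be finite")
  # drop a closing vertex if the ring was supplied closed
  m <- nrow(vertices)
  if (m > 3 && all(vertices[1, ] == vertices[m, ]))
    vertices <- vertices[-m, , drop = FALSE]
  a <- ring_area(vertices)
  if (abs(a) <= 0) stop("ROI polygon has zero area")
  if (a < 0) vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  if (!ring_is_simple(vertices))
    stop("ROI polygon is self-intersecting")
  structure(list(vertices = vertices, crs = crs), class = "roi_polygon")
}

# signed shoelace area (positive = counter-clockwise)
ring_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ring_is_simple <- function(v) {
  m <- nrow(v)
  seg <- cbind(v, v[c(2:m, 1), , drop = FALSE])
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      adjacent <- (j == i + 1) || (i == 1 && j == m)
      if (adjacent) next
      if (segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Even-odd point-in-polygon test
#'
#' @param roi A [roi_polygon()].
#' @param x,y Coordinate vectors.
#' @return Logical vector; boundary points count as inside.
#' @export
points_in_roi <- function(roi, x, y) {
  v <- roi$vertices
  m <- nrow(v)
  inside <- rep(FALSE, length(x))
  j <- m
  for (i in seq_len(m)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  # count boundary vertices as inside
  on_vertex <- rep(FALSE, length(x))
  for (i in seq_len(m)) on_vertex <- on_vertex | (x == v[i, 1] & y == v[i, 2])
  inside | on_vertex
}
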