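#' Equal-cell plant grid over a region of interest
#'
#' Splits the ROI's minimum bounding rectangle aligned to the vine-row
#' azimuth into `n_along x n_across` equal cells, one per expected plant
#' position. Cell ids run along rows first, then across (row by row), and
#' cell membership uses a half-open rule in the rotated frame so every
#' sample belongs to exactly one cell.
#'
#' @param roi A [roi_polygon()].
#' @param n_along Number of cells along the row direction.
#' @param n_across Number of cells across rows.
#' @param row_azimuth Row direction, degrees from north.
#' @return An object of class `plant_grid` with cell polygons, ids and
#'   dimensions.
#' @export
build_plant_grid <- function(roi, n_along, n_across, row_azimuth) {
  stopifnot(inherits(roi, "roi_polygon"))
  n_along <- as.integer(n_along); n_across <- as.integer(n_across)
  if (n_along < 1 || n_across < 1) stop("cell counts must be >= 1")
  a <- row_azimuth * pi / 180
  u <- c(sin(a), cos(a)); v <- c(cos(a), -sin(a))
  s <- roi$vertices %*% u
  t <- roi$vertices %*% v
  s0 <- min(s); s1 <- max(s); t0 <- min(t); t1 <- max(t)
  if (s1 - s0 <= 0 || t1 - t0 <= 0) stop("degenerate ROI")
  ds <- (s1 - s0) / n_along; dt <- (t1 - t0) / n_across

  cells <- vector("list", n_along * n_across)
  for (j in seq_len(n_across)) {
    for (i in seq_len(n_along)) {
      id <- (j - 1L) * n_along + i
      cs0 <- s0 + (i - 1) * ds; cs1 <- cs0 + ds
      ct0 <- t0 + (j - 1) * dt; ct1 <- ct0 + dt
      corners_st <- rbind(c(cs0, ct0), c(cs1, ct0), c(cs1, ct1), c(cs0, ct1))
      cells[[id]] <- list(
        id = id,
        vertices = cbind(corners_st[, 1] * u[1] + corners_st[, 2] * v[1],
                         corners_st[, 1] * u[2] + corners_st[, 2] * v[2]),
        s0 = cs0, s1 = cs1, t0 = ct0, t1 = ct1)
    }
  }
  structure(list(cells = cells, n_along = n_along, n_across = n_across,
                 row_azimuth = row_azimuth, u = u, v = v,
                 s0 = s0, t0 = t0, ds = ds, dt = dt, crs = roi$crs),
            class = "plant_grid")
}

#' @export
print.plant_grid <- function(x, ...) {
  cat(sprintf("<plant_grid> %d x %d = %d cells of %.2f x %.2f m at azimuth %.0f deg\n",
              x$n_along, x$n_across, length(x$cells), x$ds, x$dt,
              x$row_azimuth))
  invisible(x)
}

# map planar points to grid cell ids; half-open [s, s+ds) x [t, t+dt);
# 0 = outside the grid
grid_cell_ids <- function(grid, x, y) {
  s <- x * grid$u[1] + y * grid$u[2]
  t <- x * grid$v[1] + y * grid$v[2]
  i <- floor((s - grid$s0) / grid$ds) + 1
  j <- floor((t - grid$t0) / grid$dt) + 1
  ok <- i >= 1 & i <= grid$n_along & j >= 1 & j <= grid$n_across
  ifelse(ok, (j - 1) * grid$n_along + i, 0L)
}

#' Clip a raster or cloud to one grid cell
#'
#' Raster cells belong to the polygon when their center falls inside it;
#' points use the half-open boundary rule, so samples on a shared cell edge
#' are assigned to exactly one cell.
#'
#' @param data A [raster_grid()] or [point_cloud()].
#' @param cell One element of `plant_grid$cells`.
#' @param grid The [build_plant_grid()] result the cell belongs to.
#' @return The same kind of object, reduced to the cell (empty when the cell
#'   lies outside the data extent).
#' @export
clip_to_cell <- function(data, cell, grid) {
  stopifnot(inherits(grid, "plant_grid"))
  if (is_raster_grid(data)) {
    if (!identical(data$crs, grid$crs))
      stop("CRS mismatch between raster ('", data$crs, "') and grid ('",
           grid$crs, "')")
    cc <- cell_centers(data)
    ids <- grid_cell_ids(grid, as.vector(cc$x), as.vector(cc$y))
    out <- data
    out$values[matrix(ids != cell$id, nrow(data$values))] <- NA_real_
    out
  } else if (inherits(data, "point_cloud")) {
    if (!identical(data$crs, grid$crs))
      stop("CRS mismatch between cloud ('", data$crs, "') and grid ('",
           grid$crs, "')")
    ids <- grid_cell_ids(grid, data$coords[, 1], data$coords[, 2])
    subset_cloud(data, ids == cell$id)
  } else stop("data must be a raster_grid or point_cloud")
}

#' Per-plant mean CWSI records
#'
#' Averages the CWSI samples falling in each grid cell. For rasters the CWSI
#' layer itself is sampled at cell centers; for clouds the `cwsi` scalar
#' field is used. Cells with no samples are flagged (`n_samples = 0`,
#' `mean_cwsi = NA`) and are dropped from downstream regressions.
#'
#' @param grid A [build_plant_grid()] result.
#' @param data A CWSI [raster_grid()] or a [point_cloud()] with a `cwsi`
#'   scalar field.
#' @param source Label recorded in the output (e.g. `"nadir/ortho"`).
#' @return A data frame with `plant_id`, `n_samples`, `mean_cwsi`, `source`.
#' @export
per_plant_cwsi <- function(grid, data, source = "unknown") {
  stopifnot(inherits(grid, "plant_grid"))
  if (is_raster_grid(data)) {
    cc <- cell_centers(data)
    ids <- grid_cell_ids(grid, as.vector(cc$x), as.vector(cc$y))
    vals <- as.vector(data$values)
  } else if (inherits(data, "point_cloud")) {
    if (is.null(data$scalars$cwsi))
      stop("point cloud has no 'cwsi' scalar field; run cwsi() first")
    ids <- grid_cell_ids(grid, data$coords[, 1], data$coords[, 2])
    vals <- data$scalars$cwsi
  } else stop("data must be a raster_grid or point_cloud")
  keep <- ids > 0 & !is.na(vals)
  ids <- ids[keep]; vals <- vals[keep]
  nid <- length(grid$cells)
  counts <- tabulate(ids, nbins = nid)
  sums <- rep(0, nid)
  if (length(ids)) {
    agg <- tapply(vals, ids, sum)
    sums[as.integer(names(agg))] <- agg
  }
  data.frame(plant_id = seq_len(nid), n_samples = counts,
             mean_cwsi = ifelse(counts > 0, sums / pmax(counts, 1), NA_real_),
             source = source)
}

#' Volume of the 3D convex hull of a point set
#'
#' The smallest convex solid containing the points; the canopy volume
#' estimator used for comparing photogrammetric clouds against a reference
#' cloud. Requires at least 4 points in general position.
#'
#' @param points An N x 3 coordinate matrix.
#' @return Hull volume in cubic metres.
#' @export
convex_hull_volume <- function(points) {
  points <- as.matrix(points)
  if (is.null(dim(points)) || ncol(points) != 3)
    stop("points must be an N x 3 matrix")
  cpp_hull3d(points)$volume
}

#' Full 3D convex hull (volume, faces, vertices)
#'
#' @param points An N x 3 coordinate matrix (>= 4 points, not coplanar).
#' @return A list with `volume`, outward-oriented triangular `faces`
#'   (1-based row indices into `points`), and the hull `vertices` indices.
#' @export
convex_hull <- function(points) {
  points <- as.matrix(points)
  if (is.null(dim(points)) || ncol(points) != 3)
    stop("points must be an N x 3 matrix")
  cpp_hull3d(points)
}

#' Test whether points lie inside a convex hull
#'
#' @param hull A [convex_hull()] result.
#' @param points The coordinates the hull was built from.
#' @param query An M x 3 matrix of query points.
#' @param tol Planar tolerance in metres (boundary counts as inside).
#' @return Logical vector of length M.
#' @export
in_convex_hull <- function(hull, points, query, tol = 1e-9) {
  query <- as.matrix(query)
  inside <- rep(TRUE, nrow(query))
  verts <- points[hull$vertices, , drop = FALSE]
  centroid <- colMeans(verts)
  for (f in seq_len(nrow(hull$faces))) {
    tri <- points[hull$faces[f, ], , drop = FALSE]
    nrm <- c(
      (tri[2, 2] - tri[1, 2]) * (tri[3, 3] - tri[1, 3]) -
        (tri[2, 3] - tri[1, 3]) * (tri[3, 2] - tri[1, 2]),
      (tri[2, 3] - tri[1, 3]) * (tri[3, 1] - tri[1, 1]) -
        (tri[2, 1] - tri[1, 1]) * (tri[3, 3] - tri[1, 3]),
      (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
        (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1]))
    nl <- sqrt(sum(nrm^2))
    if (nl == 0) next
    nrm <- nrm / nl
    if (sum(nrm * (centroid - tri[1, ])) > 0) nrm <- -nrm  # outward
    d <- (query[, 1] - tri[1, 1]) * nrm[1] +
      (query[, 2] - tri[1, 2]) * nrm[2] +
      (query[, 3] - tri[1, 3]) * nrm[3]
    inside <- inside & d <= tol
  }
  inside
}

#' Per-plant convex-hull canopy volumes
#'
#' Clips the canopy cloud to each grid cell and computes the cell's hull
#' volume. Cells with fewer than 4 points, or with degenerate (coplanar)
#' geometry, get `NA` -- the missing-plant path.
#'
#' @param grid A [build_plant_grid()] result.
#' @param cloud The cleaned canopy [point_cloud()] (after understory
#'   removal; apply [trim_bottom()] to reference clouds when requested).
#' @param source Label recorded in the output.
#' @return A data frame with `plant_id`, `n_points`, `hull_volume`, `source`.
#' @export
plant_volumes <- function(grid, cloud, source = "unknown") {
  stopifnot(inherits(grid, "plant_grid"), inherits(cloud, "point_cloud"))
  ids <- grid_cell_ids(grid, cloud$coords[, 1], cloud$coords[, 2])
  nid <- length(grid$cells)
  vols <- rep(NA_real_, nid)
  counts <- tabulate(ids[ids > 0], nbins = nid)
  for (id in seq_len(nid)) {
    if (counts[id] < 4) next
    pts <- cloud$coords[ids == id, , drop = FALSE]
    vols[id] <- tryCatch(cpp_hull3d(pts)$volume, error = function(e) NA_real_)
  }
  data.frame(plant_id = seq_len(nid), n_points = counts, hull_volume = vols,
             source = source)
}

#' Export a plant grid as WKT polygons
#'
#' @param grid A [build_plant_grid()] result.
#' @param path Output text file (one `POLYGON` per line, prefixed by id).
#' @return `path`, invisibly.
#' @export
write_plant_grid <- function(grid, path) {
  lines <- vapply(grid$cells, function(cell) {
    ring <- rbind(cell$vertices, cell$vertices[1, ])
    sprintf("%d\tPOLYGON ((%s))", cell$id,
            paste(sprintf("%.17g %.17g", ring[, 1], ring[, 2]),
                  collapse = ", "))
  }, "")
  writeLines(c("id\twkt", lines), path)
  invisible(path)
}
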