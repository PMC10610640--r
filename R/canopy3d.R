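#' Parameters for progressive-TIN ground classification
#'
#' Defaults (1 m seed cells, 15 degree angle, 0.15 m distance, 3 iterations)
#' suit hedgerow vineyards with ~3 m row spacing; all are tunable.
#'
#' @param cell_size Seed-cell size in metres: the lowest point of each cell
#'   seeds the initial terrain model.
#' @param max_angle Maximum angle in degrees between a candidate point and
#'   the vertices of its containing terrain triangle.
#' @param max_distance Maximum vertical distance in metres from a candidate
#'   point to the terrain triangle.
#' @param n_iterations Densification rounds.
#' @return An object of class `ground_params`.
#' @export
ground_params <- function(cell_size = 1.0, max_angle = 15,
                          max_distance = 0.15, n_iterations = 3L) {
  if (any(c(cell_size, max_angle, max_distance, n_iterations) <= 0))
    stop("all ground-classifier parameters must be positive")
  if (max_angle >= 90) stop("max_angle must be below 90 degrees")
  structure(list(cell_size = cell_size, max_angle = max_angle,
                 max_distance = max_distance,
                 n_iterations = as.integer(n_iterations)),
            class = "ground_params")
}

#' Parameters for statistical outlier removal
#'
#' @param k_neighbors Number of nearest neighbours considered per point.
#' @param sigma_multiplier A point is an outlier when its mean neighbour
#'   distance exceeds the global mean by this many standard deviations.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(k_neighbors = 8L, sigma_multiplier = 2.0) {
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  if (sigma_multiplier <= 0) stop("sigma_multiplier must be > 0")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 sigma_multiplier = sigma_multiplier),
            class = "noise_params")
}

# deduplicate planimetric positions (Delaunay needs distinct xy); keeps the
# first occurrence
dedupe_xy <- function(x, y) {
  !duplicated(paste(sprintf("%.9f", x), sprintf("%.9f", y)))
}

#' Classify ground points by progressive TIN densification
#'
#' Divides the cloud into planimetric cells, takes the lowest point of each
#' cell as a terrain seed, triangulates the seeds, and then iteratively
#' accepts unassigned points as ground when they are (a) within
#' `max_distance` vertically of their containing terrain triangle and (b)
#' subtend at most `max_angle` (measured from the horizontal) to each of the
#' triangle's vertices. The terrain is retriangulated after every round.
#' Points never accepted are labelled `canopy`.
#'
#' @param cloud A [point_cloud()] with at least 3 non-collinear points.
#' @param params A [ground_params()].
#' @return The cloud with `class_label` set to `ground`/`canopy` for every
#'   point (order unchanged), plus the fitted terrain as attribute
#'   `"terrain"` (a TIN usable with [terrain_height()]).
#' @export
classify_ground <- function(cloud, params = ground_params()) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  if (n < 3) stop("cannot triangulate terrain from ", n, " point(s)")
  x <- cloud$coords[, 1]; y <- cloud$coords[, 2]; z <- cloud$coords[, 3]

  cs <- params$cell_size
  key <- paste(floor(x / cs), floor(y / cs))
  lowest <- tapply(seq_len(n), key, function(i) i[which.min(z[i])])
  is_ground <- rep(FALSE, n)
  is_ground[unlist(lowest)] <- TRUE

  tan_max <- tan(params$max_angle * pi / 180)
  # virtual corner vertices let the TIN cover the whole footprint, so border
  # points are judged by the thresholds instead of falling outside the hull
  pad <- cs
  corner_x <- c(min(x) - pad, max(x) + pad, max(x) + pad, min(x) - pad)
  corner_y <- c(min(y) - pad, min(y) - pad, max(y) + pad, max(y) + pad)
  tin <- NULL
  for (iter in seq_len(params$n_iterations)) {
    g <- which(is_ground)
    keep <- dedupe_xy(x[g], y[g])
    g <- g[keep]
    if (length(g) < 3) stop("degenerate geometry: fewer than 3 terrain seeds")
    if (qr(cbind(x[g] - mean(x[g]), y[g] - mean(y[g])))$rank < 2)
      stop("degenerate geometry: terrain seeds are collinear")
    coef <- qr.coef(qr(cbind(1, x[g], y[g])), z[g])
    corner_z <- coef[1] + coef[2] * corner_x + coef[3] * corner_y
    tx <- c(x[g], corner_x); ty <- c(y[g], corner_y)
    tz <- c(z[g], corner_z)
    tri <- cpp_delaunay(tx, ty)
    tin <- list(x = tx, y = ty, z = tz, tri = tri)
    cand <- which(!is_ground)
    if (!length(cand)) break
    loc <- cpp_tin_interp(tin$x, tin$y, tin$z, tin$tri, x[cand], y[cand])
    inside <- !is.na(loc$tri)
    ok <- rep(FALSE, length(cand))
    ci <- which(inside)
    if (length(ci)) {
      dz <- abs(z[cand[ci]] - loc$z[ci])
      verts <- tin$tri[loc$tri[ci], , drop = FALSE]
      ang_ok <- rep(TRUE, length(ci))
      for (vcol in 1:3) {
        vi <- verts[, vcol]
        horiz <- sqrt((x[cand[ci]] - tin$x[vi])^2 +
                        (y[cand[ci]] - tin$y[vi])^2)
        vert <- abs(z[cand[ci]] - tin$z[vi])
        ang_ok <- ang_ok & (vert <= tan_max * pmax(horiz, 1e-9))
      }
      ok[ci] <- (dz <= params$max_distance) & ang_ok
    }
    if (!any(ok)) break
    is_ground[cand[ok]] <- TRUE
  }
  out <- cloud
  out$class_label <- factor(ifelse(is_ground, "ground", "canopy"),
                            levels = cloud_classes())
  attr(out, "terrain") <- structure(tin, class = "terrain_tin")
  out
}

#' Interpolate terrain height at planimetric positions
#'
#' Linear interpolation on the ground TIN produced by [classify_ground()].
#'
#' @param tin A `terrain_tin` (attribute `"terrain"` of a classified cloud).
#' @param x,y Coordinates in metres.
#' @return Terrain elevations; `NA` outside the triangulated hull.
#' @export
terrain_height <- function(tin, x, y) {
  stopifnot(inherits(tin, "terrain_tin"))
  cpp_tin_interp(tin$x, tin$y, tin$z, tin$tri, x, y)$z
}

#' Remove outlier points by k-nearest-neighbour statistics
#'
#' Statistical outlier removal: a point is discarded when its mean distance
#' to its `k_neighbors` nearest neighbours exceeds the global mean of that
#' quantity by `sigma_multiplier` standard deviations. Retained points keep
#' their order; the removed points (labelled `noise`) are attached as
#' attribute `"noise_points"`.
#'
#' @param cloud A [point_cloud()] with more than `k_neighbors` points.
#' @param params A [noise_params()].
#' @return The filtered `point_cloud`.
#' @export
filter_noise <- function(cloud, params = noise_params()) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  if (n <= params$k_neighbors)
    stop(sprintf("need more than k_neighbors = %d points, got %d",
                 params$k_neighbors, n))
  d <- cpp_knn_meandist(cloud$coords, params$k_neighbors)
  thr <- mean(d) + params$sigma_multiplier * stats::sd(d)
  keep <- d <= thr
  removed <- subset_cloud(cloud, !keep)
  if (n_points(removed) > 0)
    removed$class_label <- factor(rep("noise", n_points(removed)),
                                  levels = cloud_classes())
  out <- subset_cloud(cloud, keep)
  attr(out, "noise_points") <- removed
  out
}

heights_above_terrain <- function(cloud, terrain) {
  if (inherits(terrain, "terrain_tin"))
    terrain_height(terrain, cloud$coords[, 1], cloud$coords[, 2])
  else if (is.function(terrain))
    terrain(cloud$coords[, 1], cloud$coords[, 2])
  else stop("terrain must be a terrain_tin or a function(x, y) -> z")
}

#' Remove understory points below a minimum canopy height
#'
#' Rule-based replacement for manual cloud editing: drops soil remnants,
#' trunks and low vegetation by removing every point whose height above the
#' interpolated terrain is below `min_height` (mirroring the 0.5 m canopy
#' height threshold of the 2D branch). Points outside the terrain hull have
#' no defined height and are dropped; their count is reported via a message.
#'
#' @param cloud A [point_cloud()] (typically the canopy-labelled subset).
#' @param terrain A `terrain_tin` from [classify_ground()], or a
#'   `function(x, y)` returning terrain elevation.
#' @param min_height Minimum height above terrain in metres.
#' @return The filtered `point_cloud`, order preserved.
#' @export
remove_understory <- function(cloud, terrain, min_height = 0.5) {
  if (min_height < 0) stop("min_height must be >= 0")
  zt <- heights_above_terrain(cloud, terrain)
  h <- cloud$coords[, 3] - zt
  outside <- is.na(h)
  if (any(outside))
    message(sum(outside), " point(s) outside the terrain hull were dropped")
  subset_cloud(cloud, !outside & h >= min_height)
}

#' Trim the bottom slice of a canopy cloud
#'
#' Removes points within `trim_m` of the lowest canopy height above terrain.
#' With the 0.20 m default this reproduces the adjustment used to align a
#' denser reference (LiDAR-like) cloud, whose canopy reaches lower, with
#' photogrammetric clouds.
#'
#' @param cloud A canopy [point_cloud()].
#' @param terrain A `terrain_tin` or `function(x, y)`.
#' @param trim_m Thickness of the bottom slice to drop, metres (>= 0).
#' @return The trimmed `point_cloud`.
#' @export
trim_bottom <- function(cloud, terrain, trim_m = 0.20) {
  if (trim_m < 0) stop("trim_m must be >= 0")
  if (trim_m == 0) return(cloud)
  zt <- heights_above_terrain(cloud, terrain)
  h <- cloud$coords[, 3] - zt
  inside <- !is.na(h)
  if (!any(inside)) {
    warning("no points with defined height; returning empty cloud")
    return(subset_cloud(cloud, logical(n_points(cloud))))
  }
  min_h <- min(h[inside])
  keep <- inside & h >= min_h + trim_m
  if (!any(keep)) warning("trim_m exceeds the canopy depth; cloud is empty")
  subset_cloud(cloud, keep)
}

#' Segment the top surface of a point cloud
#'
#' Per planimetric cell of `cell_size`, keeps the points within `depth_m` of
#' the cell's maximum elevation -- the part of the canopy a nadir orthomosaic
#' sees. Deterministic; output point order follows the input.
#'
#' @param cloud A [point_cloud()] with at least one point.
#' @param cell_size Planimetric cell size in metres.
#' @param depth_m Vertical window below each cell's top, metres.
#' @return The top-surface subset of `cloud`.
#' @export
segment_top <- function(cloud, cell_size = 0.25, depth_m = 0.20) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (cell_size <= 0 || depth_m <= 0)
    stop("cell_size and depth_m must be positive")
  if (n_points(cloud) == 0) stop("cannot segment an empty cloud")
  x <- cloud$coords[, 1]; y <- cloud$coords[, 2]; z <- cloud$coords[, 3]
  key <- paste(floor(x / cell_size), floor(y / cell_size))
  zmax <- stats::ave(z, key, FUN = max)
  subset_cloud(cloud, z >= zmax - depth_m)
}
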