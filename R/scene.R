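#' Synthetic vineyard scene configuration
#'
#' Describes the simulated vineyard every downstream stage is tested on:
#' VSP-style hedgerow vines on a regular row grid (2.5 m between plants,
#' 3 m between rows, NE-SW rows by default), canopy solids modelled as
#' ellipsoids spanning a fixed height interval above a gently inclined
#' terrain, soil warmer than canopy, a vertical canopy-temperature gradient
#' (cooler at the top), Gaussian sensor noise, and occasional missing plants.
#'
#' @param n_rows Number of vine rows.
#' @param plants_per_row Plants along each row.
#' @param row_spacing Distance between rows in metres.
#' @param plant_spacing Distance between plants along a row in metres.
#' @param row_azimuth Row direction in degrees from north (45 = NE-SW).
#' @param canopy_height Vertical extent of the canopy solid in metres.
#' @param canopy_base Height of the canopy bottom above terrain in metres.
#' @param canopy_radii Ellipsoid semi-axes `(along-row, across-row)` in
#'   metres.
#' @param soil_temp_mean,soil_temp_sd Soil surface temperature field, degC.
#' @param canopy_top_temp_mean Canopy temperature at the very top, degC.
#' @param vertical_temp_gradient degC per metre of depth below the canopy
#'   top; positive means warmer toward the base.
#' @param temp_noise_sd Thermal sensor noise, degC.
#' @param missing_plant_prob Probability that a plant position is empty.
#' @param plant_scale_sd Log-sd of a per-plant multiplicative size factor on
#'   the canopy radii and height (vigor variability); the canopy base stays
#'   fixed, as the fruiting wire sets it.
#' @param point_density Canopy points per square metre of canopy surface
#'   area; points sample the canopy envelope, as photogrammetric and LiDAR
#'   sensors do.
#' @param ground_point_density Ground points per square metre.
#' @param cell_size Raster resolution in metres per cell.
#' @param terrain_slope_x,terrain_slope_y Terrain plane slopes (dz/dx,
#'   dz/dy); the default is a gentle ~2 degree incline so ground
#'   classification is non-trivially exercised.
#' @param terrain_z0 Terrain elevation at the scene origin, metres.
#' @param margin Flat buffer around the planted block, metres.
#' @param seed Integer seed; the scene is a pure function of this config.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_rows = 4L, plants_per_row = 6L,
                         row_spacing = 3.0, plant_spacing = 2.5,
                         row_azimuth = 45, canopy_height = 1.8,
                         canopy_base = 0.5, canopy_radii = c(1.1, 0.5),
                         soil_temp_mean = 45, soil_temp_sd = 1.5,
                         canopy_top_temp_mean = 32,
                         vertical_temp_gradient = 2.0,
                         temp_noise_sd = 0.5, missing_plant_prob = 0.05,
                         plant_scale_sd = 0.15,
                         point_density = 250, ground_point_density = 50,
                         cell_size = 0.10, terrain_slope_x = 0.03,
                         terrain_slope_y = 0.015, terrain_z0 = 100,
                         margin = 2.0, seed = 1L) {
  cfg <- list(n_rows = as.integer(n_rows),
              plants_per_row = as.integer(plants_per_row),
              row_spacing = row_spacing, plant_spacing = plant_spacing,
              row_azimuth = row_azimuth, canopy_height = canopy_height,
              canopy_base = canopy_base,
              canopy_radii = as.numeric(canopy_radii),
              soil_temp_mean = soil_temp_mean, soil_temp_sd = soil_temp_sd,
              canopy_top_temp_mean = canopy_top_temp_mean,
              vertical_temp_gradient = vertical_temp_gradient,
              temp_noise_sd = temp_noise_sd,
              missing_plant_prob = missing_plant_prob,
              plant_scale_sd = plant_scale_sd,
              point_density = point_density,
              ground_point_density = ground_point_density,
              cell_size = cell_size, terrain_slope_x = terrain_slope_x,
              terrain_slope_y = terrain_slope_y, terrain_z0 = terrain_z0,
              margin = margin, seed = as.integer(seed))
  with(cfg, {
    if (n_rows < 1 || plants_per_row < 1) stop("need at least one plant")
    if (any(c(row_spacing, plant_spacing, canopy_height, canopy_radii,
              point_density, ground_point_density, cell_size) <= 0))
      stop("spacings, densities, radii, heights and cell_size must be > 0")
    if (canopy_base < 0) stop("canopy_base must be >= 0")
    if (missing_plant_prob < 0 || missing_plant_prob > 1)
      stop("missing_plant_prob must lie in [0, 1]")
    if (any(c(soil_temp_sd, temp_noise_sd, plant_scale_sd) < 0))
      stop("noise sd must be >= 0")
    if (length(canopy_radii) != 2) stop("canopy_radii must be (along, across)")
  })
  structure(cfg, class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("<scene_config> %d rows x %d plants, %.1fm x %.1fm spacing, azimuth %.0f deg, seed %d\n",
              x$n_rows, x$plants_per_row, x$row_spacing, x$plant_spacing,
              x$row_azimuth, x$seed))
  invisible(x)
}

scene_axes <- function(config) {
  a <- config$row_azimuth * pi / 180
  list(u = c(sin(a), cos(a)),    # along-row unit vector
       v = c(cos(a), -sin(a)))   # across-row unit vector
}

terrain_z <- function(config, x, y) {
  config$terrain_z0 + config$terrain_slope_x * x + config$terrain_slope_y * y
}

#' Volume of an ellipsoid segment between two horizontal planes
#'
#' Closed form for the solid `x^2/a^2 + y^2/b^2 + z^2/c^2 <= 1` between
#' heights `z_lo` and `z_hi` (relative to the ellipsoid center):
#' `pi*a*b * [z - z^3/(3 c^2)]` evaluated between the clamped bounds.
#'
#' @param a,b,c Semi-axes in metres.
#' @param z_lo,z_hi Cut heights relative to the center; defaults give the
#'   full ellipsoid `4/3 pi a b c`.
#' @return Volume in cubic metres.
#' @export
ellipsoid_segment_volume <- function(a, b, c, z_lo = -c, z_hi = c) {
  z1 <- max(z_lo, -c); z2 <- min(z_hi, c)
  if (z2 <= z1) return(0)
  anti <- function(z) z - z^3 / (3 * c^2)
  pi * a * b * (anti(z2) - anti(z1))
}

# Thomsen approximation of the ellipsoid surface area (used only to convert
# the per-surface-area point density into a point count)
ellipsoid_surface_area <- function(a, b, c) {
  p <- 1.6075
  4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p)
}

plant_layout <- function(config) {
  ax <- scene_axes(config)
  n_along <- config$plants_per_row
  n_across <- config$n_rows
  grid <- expand.grid(i = seq_len(n_along), j = seq_len(n_across))
  s <- (grid$i - (n_along + 1) / 2) * config$plant_spacing
  t <- (grid$j - (n_across + 1) / 2) * config$row_spacing
  data.frame(plant_id = (grid$j - 1L) * n_along + grid$i,
             x = s * ax$u[1] + t * ax$v[1],
             y = s * ax$u[2] + t * ax$v[2])[order(grid$j, grid$i), ]
}

scene_roi <- function(config) {
  ax <- scene_axes(config)
  hs <- config$plants_per_row * config$plant_spacing / 2
  ht <- config$n_rows * config$row_spacing / 2
  corners_st <- rbind(c(-hs, -ht), c(hs, -ht), c(hs, ht), c(-hs, ht))
  roi_polygon(cbind(corners_st[, 1] * ax$u[1] + corners_st[, 2] * ax$v[1],
                    corners_st[, 1] * ax$u[2] + corners_st[, 2] * ax$v[2]),
              crs = "local metric")
}

# area-uniform sample on the ellipsoid surface (rejection over the sphere
# map), truncated below z_min_rel (relative to center); returns an n x 3
# matrix. Surface sampling emulates what SfM photogrammetry and LiDAR
# observe: the canopy envelope, not its interior.
sample_ellipsoid_surface <- function(n, a, b, c, z_min_rel = -Inf,
                                     s_max = Inf, t_max = Inf) {
  m_max <- max(b * c, a * c, a * b)
  out <- matrix(numeric(0), 0, 3)
  while (nrow(out) < n) {
    m <- max(32L, 2L * (n - nrow(out)))
    g <- matrix(stats::rnorm(3 * m), m, 3)
    g <- g / sqrt(rowSums(g^2))
    # local area element of the sphere -> ellipsoid map
    w <- sqrt((g[, 1] * b * c)^2 + (g[, 2] * a * c)^2 + (g[, 3] * a * b)^2)
    acc <- stats::runif(m) < w / m_max
    p <- cbind(a * g[acc, 1], b * g[acc, 2], c * g[acc, 3])
    p <- p[p[, 3] >= z_min_rel & abs(p[, 1]) <= s_max & abs(p[, 2]) <= t_max,
           , drop = FALSE]
    out <- rbind(out, p)
  }
  out[seq_len(n), , drop = FALSE]
}

# hedged-ellipsoid volume: full ellipsoid minus the caps cut off by the
# vertical hedging planes at +/- s_max (along row) and +/- t_max (across);
# the simultaneous corner cut is negligible at vineyard geometries
hedged_ellipsoid_volume <- function(a, b, c, s_max, t_max) {
  v <- ellipsoid_segment_volume(a, b, c)
  if (a > s_max) v <- v - 2 * ellipsoid_segment_volume(b, c, a, s_max, a)
  if (b > t_max) v <- v - 2 * ellipsoid_segment_volume(a, c, b, t_max, b)
  max(v, 0)
}

#' Generate a synthetic vineyard scene with ground truth
#'
#' A pure function of its [scene_config()] (the seed included): identical
#' configs give identical scenes. Randomness is drawn in a fixed documented
#' order -- plant presence, per-plant size factors, canopy points per plant
#' in id order, ground points, then raster sensor noise.
#'
#' @param config A [scene_config()].
#' @return An object of class `vineyard_scene`: rasters `dsm`, `dtm`,
#'   `thermal` ([raster_grid()]), `cloud` (a [point_cloud()] with truth class
#'   labels and Celsius temperatures), `roi`, and `plant_truth` (a data frame
#'   with `plant_id`, `x`, `y`, `present`, `true_volume`).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  plants <- plant_layout(config)
  np <- nrow(plants)
  plants$present <- stats::runif(np) >= config$missing_plant_prob
  plants$scale <- exp(stats::rnorm(np, 0, config$plant_scale_sd))
  # per-plant canopy ellipsoid: radii and height scale with vigor, the base
  # (fruiting-wire height) stays put
  pa <- config$canopy_radii[1] * plants$scale
  pb <- config$canopy_radii[2] * plants$scale
  pc_ <- config$canopy_height * plants$scale / 2
  # hedging planes: canopies are trimmed at half the plant and row spacing,
  # as mechanical VSP hedging keeps vines inside their slot
  s_hedge <- config$plant_spacing / 2
  t_hedge <- config$row_spacing / 2
  plants$true_volume <- ifelse(
    plants$present,
    vapply(seq_len(np), function(k)
      hedged_ellipsoid_volume(pa[k], pb[k], pc_[k], s_hedge, t_hedge), 0),
    0)

  roi <- scene_roi(config)
  ext <- apply(roi$vertices, 2, range)
  xmin <- ext[1, 1] - config$margin; xmax <- ext[2, 1] + config$margin
  ymin <- ext[1, 2] - config$margin; ymax <- ext[2, 2] + config$margin

  z_center_off <- config$canopy_base + pc_         # per-plant center height
  plant_top_z <- terrain_z(config, plants$x, plants$y) +
    config$canopy_base + 2 * pc_

  # canopy points: area-uniform on each present plant's canopy envelope
  ax <- scene_axes(config)
  canopy_pts <- vector("list", np)
  for (k in seq_len(np)) {
    if (!plants$present[k]) next
    n_k <- max(10L, round(config$point_density *
                            ellipsoid_surface_area(pa[k], pb[k], pc_[k])))
    loc <- sample_ellipsoid_surface(n_k, pa[k], pb[k], pc_[k],
                                    z_min_rel = config$canopy_base - z_center_off[k],
                                    s_max = s_hedge, t_max = t_hedge)
    # rotate local (along, across) into world xy
    wx <- plants$x[k] + loc[, 1] * ax$u[1] + loc[, 2] * ax$v[1]
    wy <- plants$y[k] + loc[, 1] * ax$u[2] + loc[, 2] * ax$v[2]
    wz <- terrain_z(config, plants$x[k], plants$y[k]) + z_center_off[k] + loc[, 3]
    depth <- plant_top_z[k] - wz
    temp <- config$canopy_top_temp_mean +
      config$vertical_temp_gradient * depth +
      stats::rnorm(n_k, 0, config$temp_noise_sd)
    canopy_pts[[k]] <- cbind(wx, wy, wz, temp)
  }
  canopy_pts <- do.call(rbind, canopy_pts)
  if (is.null(canopy_pts)) canopy_pts <- matrix(numeric(0), 0, 4)

  # ground points: uniform over the scene footprint, exactly on the terrain
  area <- (xmax - xmin) * (ymax - ymin)
  ng <- max(100L, round(config$ground_point_density * area))
  gx <- stats::runif(ng, xmin, xmax)
  gy <- stats::runif(ng, ymin, ymax)
  gz <- terrain_z(config, gx, gy)
  gtemp <- config$soil_temp_mean + stats::rnorm(ng, 0, config$soil_temp_sd) +
    stats::rnorm(ng, 0, config$temp_noise_sd)

  nc <- nrow(canopy_pts)
  coords <- rbind(cbind(gx, gy, gz), canopy_pts[, 1:3, drop = FALSE])
  temperature <- c(gtemp, canopy_pts[, 4])
  class_label <- c(rep("ground", ng), rep("canopy", nc))
  color <- rbind(matrix(rep(c(150L, 110L, 70L), each = ng), ncol = 3),
                 matrix(rep(c(60L, 120L, 60L), each = nc), ncol = 3))
  cloud <- point_cloud(coords, temperature = temperature,
                       temp_unit = "celsius", color = color,
                       class_label = class_label, crs = roi$crs)

  # rasters on cell centers (top-left origin, north-up)
  ncol_ <- max(1L, ceiling((xmax - xmin) / config$cell_size))
  nrow_ <- max(1L, ceiling((ymax - ymin) / config$cell_size))
  dtm <- raster_grid(matrix(0, nrow_, ncol_), xmin = xmin,
                     ymax = ymin + nrow_ * config$cell_size,
                     dx = config$cell_size, dy = config$cell_size,
                     crs = roi$crs)
  cc_xy <- cell_centers(dtm)
  dtm$values <- terrain_z(config, cc_xy$x, cc_xy$y)
  surf <- dtm$values
  canopy_cell <- matrix(FALSE, nrow_, ncol_)
  for (k in seq_len(np)) {
    if (!plants$present[k]) next
    ddx <- as.vector(cc_xy$x) - plants$x[k]
    ddy <- as.vector(cc_xy$y) - plants$y[k]
    s <- ddx * ax$u[1] + ddy * ax$u[2]
    t <- ddx * ax$v[1] + ddy * ax$v[2]
    r2 <- (s / pa[k])^2 + (t / pb[k])^2
    inside <- r2 < 1 & abs(s) <= s_hedge & abs(t) <= t_hedge
    top <- terrain_z(config, plants$x[k], plants$y[k]) + z_center_off[k] +
      pc_[k] * sqrt(pmax(1 - r2, 0))
    upd <- inside & top > surf
    surf[upd] <- top[upd]
    canopy_cell <- canopy_cell | matrix(upd, nrow_, ncol_)
  }
  dsm <- dtm
  dsm$values <- matrix(pmax(as.vector(surf), as.vector(dtm$values)),
                       nrow_, ncol_)

  thermal <- dtm
  soil_field <- config$soil_temp_mean +
    stats::rnorm(nrow_ * ncol_, 0, config$soil_temp_sd)
  noise <- stats::rnorm(nrow_ * ncol_, 0, config$temp_noise_sd)
  # per-cell canopy temperature: depth below the top of the plant whose
  # footprint covers the cell (governing plant taken as the nearest center)
  tvals <- soil_field
  can_idx <- which(as.vector(canopy_cell))
  if (length(can_idx)) {
    px <- as.vector(cc_xy$x)[can_idx]; py <- as.vector(cc_xy$y)[can_idx]
    nearest <- apply(cbind(px, py), 1, function(p)
      which.min((plants$x - p[1])^2 + (plants$y - p[2])^2))
    depth <- plant_top_z[nearest] - as.vector(dsm$values)[can_idx]
    tvals[can_idx] <- config$canopy_top_temp_mean +
      config$vertical_temp_gradient * pmax(depth, 0)
  }
  thermal$values <- matrix(tvals + noise, nrow_, ncol_)

  structure(list(dsm = dsm, dtm = dtm, thermal = thermal, cloud = cloud,
                 roi = roi, plant_truth = plants, config = config),
            class = "vineyard_scene")
}

#' @export
print.vineyard_scene <- function(x, ...) {
  cat(sprintf("<vineyard_scene> %d plants (%d present), %d cloud points, %d x %d raster cells\n",
              nrow(x$plant_truth), sum(x$plant_truth$present),
              n_points(x$cloud), nrow(x$dsm$values), ncol(x$dsm$values)))
  invisible(x)
}

#' Write a scene to disk and return its manifest
#'
#' Writes the rasters as GeoTIFF, the cloud as lossless text plus LAS
#' (coordinates and truth classes), the ROI as WKT, the truth table as CSV,
#' the config as flat key-value text, and a JSON manifest listing every file
#' with the seed and a config digest.
#'
#' @param scene A [generate_scene()] result.
#' @param dir Output directory (created if missing).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
scene_to_disk <- function(scene, dir) {
  stopifnot(inherits(scene, "vineyard_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(dtm = "dtm.tif", dsm = "dsm.tif", thermal = "thermal.tif",
                cloud_xyz = "cloud.xyz", cloud_las = "cloud.las",
                roi = "roi.wkt", truth = "plant_truth.csv",
                config = "config.txt")
  fp <- function(nm) file.path(dir, paths[[nm]])
  write_raster(scene$dtm, fp("dtm"), dtype = "float64")
  write_raster(scene$dsm, fp("dsm"), dtype = "float64")
  write_raster(scene$thermal, fp("thermal"), dtype = "float64")
  write_cloud(scene$cloud, fp("cloud_xyz"), format = "xyz")
  write_cloud(scene$cloud, fp("cloud_las"), format = "las",
              attributes = "class_label")
  v <- scene$roi$vertices
  ring <- rbind(v, v[1, ])
  writeLines(sprintf("POLYGON ((%s))",
                     paste(sprintf("%.17g %.17g", ring[, 1], ring[, 2]),
                           collapse = ", ")), fp("roi"))
  utils::write.csv(scene$plant_truth, fp("truth"), row.names = FALSE)
  write_flat_config(unclass(scene$config), fp("config"))
  manifest <- list(seed = scene$config$seed,
                   config_md5 = unname(tools::md5sum(fp("config"))),
                   files = lapply(paths, identity))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Reload a scene directory written by [scene_to_disk()]
#'
#' @param dir Directory containing a scene manifest.
#' @return A list with `dsm`, `dtm`, `thermal`, `cloud`, `roi`,
#'   `plant_truth`, and `config`.
#' @export
scene_from_disk <- function(dir) {
  fp <- function(nm) file.path(dir, nm)
  cfg <- read_flat_config(fp("config.txt"))
  roi_txt <- readLines(fp("roi.wkt"))
  nums <- as.numeric(strsplit(gsub("[^0-9eE+.,[:space:]-]", "", roi_txt),
                              "[,[:space:]]+")[[1]])
  nums <- nums[!is.na(nums)]
  ring <- matrix(nums, ncol = 2, byrow = TRUE)
  list(dsm = read_raster(fp("dsm.tif")), dtm = read_raster(fp("dtm.tif")),
       thermal = read_raster(fp("thermal.tif")),
       cloud = read_cloud(fp("cloud.xyz"), format = "xyz"),
       roi = roi_polygon(ring),
       plant_truth = utils::read.csv(fp("plant_truth.csv")),
       config = cfg)
}

write_flat_config <- function(cfg, path) {
  fmt <- function(v) paste(vapply(v, function(x)
    if (is.numeric(x)) sprintf("%.17g", x) else as.character(x), ""),
    collapse = " ")
  writeLines(sprintf("%s: %s", names(cfg), vapply(cfg, fmt, "")), path)
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  keys <- sub(":.*$", "", lines)
  vals <- lapply(trimws(sub("^[^:]*:", "", lines)), function(s) {
    parts <- strsplit(s, "\\s+")[[1]]
    nums <- suppressWarnings(as.numeric(parts))
    if (!anyNA(nums)) nums else s
  })
  stats::setNames(vals, trimws(keys))
}
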