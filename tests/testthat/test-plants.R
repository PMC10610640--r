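test_that("build_plant_grid partitions the ROI rectangle into equal cells", {
  grid <- build_plant_grid(square_roi(10), 2, 2, row_azimuth = 0)
  expect_length(grid$cells, 4)
  areas <- vapply(grid$cells, function(cell)
    abs(vinecwsi:::ring_area(cell$vertices)), 0)
  expect_equal(areas, rep(25, 4))
  expect_equal(sum(areas), 100)

  # the study-style configuration: 17 x 3 = 51 polygons
  grid51 <- build_plant_grid(square_roi(30), 17, 3, row_azimuth = 45)
  expect_length(grid51$cells, 51)

  # rotation preserves cell areas and aligns edges with the azimuth
  grid45 <- build_plant_grid(square_roi(10), 2, 2, row_azimuth = 45)
  areas45 <- vapply(grid45$cells, function(cell)
    abs(vinecwsi:::ring_area(cell$vertices)), 0)
  expect_equal(sum(areas45), sum(areas45[1]) * 4)
  e <- grid45$cells[[1]]$vertices[2, ] - grid45$cells[[1]]$vertices[1, ]
  ang <- atan2(e[1], e[2]) * 180 / pi
  expect_equal(ang %% 90, 45)
  expect_error(build_plant_grid(square_roi(10), 0, 2, 0), ">= 1")
})

test_that("cell membership is half-open: edge samples land in one cell", {
  grid <- build_plant_grid(square_roi(10), 2, 2, row_azimuth = 0)
  # a point exactly on the shared interior edge
  ids <- vinecwsi:::grid_cell_ids(grid, c(5, 5, 0, 10), c(2, 7, 0, 10))
  expect_false(any(ids == 0 & c(TRUE, TRUE, TRUE, FALSE)))
  counts <- vapply(seq_along(grid$cells), function(id) sum(ids[1:3] == id), 0L)
  expect_equal(sum(counts), 3)  # each interior/edge point in exactly one cell
  # partition oracle: random in-ROI points are assigned exactly once
  set.seed(41)
  xs <- runif(500, 0, 10); ys <- runif(500, 0, 10)
  ids <- vinecwsi:::grid_cell_ids(grid, xs, ys)
  expect_true(all(ids >= 1 & ids <= 4))
})

test_that("clip_to_cell subsets rasters and clouds consistently", {
  grid <- build_plant_grid(square_roi(10), 2, 2, row_azimuth = 0)
  r <- raster_grid(matrix(1:100, 10, 10), xmin = 0, ymax = 10, dx = 1, dy = 1,
                   crs = "local metric")
  clipped <- clip_to_cell(r, grid$cells[[1]], grid)
  expect_equal(sum(!is.na(clipped$values)), 25)
  set.seed(42)
  pc <- point_cloud(cbind(runif(200, 0, 10), runif(200, 0, 10), 0))
  per_cell <- vapply(grid$cells, function(cell)
    n_points(clip_to_cell(pc, cell, grid)), 0L)
  expect_equal(sum(per_cell), 200)  # count conservation across the partition
  # a cell fully outside the data extent is empty, not an error
  far <- point_cloud(cbind(runif(10, 50, 60), runif(10, 50, 60), 0))
  expect_equal(n_points(clip_to_cell(far, grid$cells[[1]], grid)), 0)
  wrong <- point_cloud(matrix(0, 1, 3), crs = "other")
  expect_error(clip_to_cell(wrong, grid$cells[[1]], grid), "CRS")
})

test_that("per_plant_cwsi averages samples and flags empty cells", {
  grid <- build_plant_grid(square_roi(10), 2, 2, row_azimuth = 0)
  pc <- point_cloud(cbind(c(2, 3, 7, 8), c(2, 2, 2, 8), 0),
                    scalars = list(cwsi = c(0.2, 0.4, 0.6, 0.9)))
  rec <- per_plant_cwsi(grid, pc, source = "cloud")
  # azimuth 0: the along-row axis points north, so cell 3 is the south-east
  expect_equal(rec$mean_cwsi[rec$plant_id == 1], 0.3)  # mean(0.2, 0.4)
  expect_equal(rec$mean_cwsi[rec$plant_id == 3], 0.6)
  empty <- rec[rec$n_samples == 0, ]
  expect_true(all(is.na(empty$mean_cwsi)))
  expect_error(per_plant_cwsi(grid, point_cloud(matrix(0, 1, 3))), "cwsi")
})

test_that("per-plant cloud means match the analytic field under the index", {
  cfg <- small_scene_config(seed = 15, temp_noise_sd = 0, soil_temp_sd = 0,
                            missing_plant_prob = 0)
  sc <- generate_scene(cfg)
  canopy <- subset_cloud(sc$cloud, sc$cloud$class_label == "canopy")
  refs <- structure(list(t_wet = 32, t_dry = 42, tail_fraction = 0.005,
                         n_tail = 1L), class = "reference_temps")
  cw <- cwsi(canopy, refs)
  grid <- build_plant_grid(sc$roi, cfg$plants_per_row, cfg$n_rows,
                           cfg$row_azimuth)
  rec <- per_plant_cwsi(grid, cw)
  # affine identity: mean CWSI per plant == cwsi(mean temperature per plant)
  ids <- vinecwsi:::grid_cell_ids(grid, canopy$coords[, 1], canopy$coords[, 2])
  for (id in unique(rec$plant_id[rec$n_samples > 0])) {
    expect_equal(rec$mean_cwsi[rec$plant_id == id],
                 cwsi(mean(canopy$temperature[ids == id]), refs),
                 tolerance = 1e-10)
  }
})

test_that("convex hull volumes match closed forms and a Monte-Carlo oracle", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_volume(cube), 1.0)
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(convex_hull_volume(tet), 1 / 6)

  set.seed(43)
  g <- matrix(rnorm(3e4), ncol = 3)
  ball <- g / sqrt(rowSums(g^2)) * runif(1e4)^(1 / 3)
  hull <- convex_hull(ball)
  # membership oracle: Monte-Carlo volume of the hull via half-space tests
  q <- cbind(runif(2e4, -1, 1), runif(2e4, -1, 1), runif(2e4, -1, 1))
  v_mc <- mean(in_convex_hull(hull, ball, q)) * 8
  expect_equal(hull$volume, v_mc, tolerance = 0.02)

  # degenerate geometry errors carry the point count
  expect_error(convex_hull_volume(tet[1:3, ]), "4 points, got 3")
  coplanar <- cbind(runif(20), runif(20), 0.5)
  expect_error(convex_hull_volume(coplanar), "coplanar")
})

test_that("hull volume is monotone under point addition", {
  set.seed(44)
  pts <- matrix(rnorm(60), ncol = 3)
  v <- convex_hull_volume(pts)
  for (i in 1:20) {
    pts <- rbind(pts, rnorm(3, sd = 1.5))
    v2 <- convex_hull_volume(pts)
    expect_gte(v2, v - 1e-12)
    v <- v2
  }
})

test_that("per-plant hull volumes recover the truth; missing plants stay empty", {
  cfg <- small_scene_config(seed = 16, missing_plant_prob = 0)
  sc <- generate_scene(cfg)
  # force one plant out to exercise the missing-plant path
  cfg_missing <- small_scene_config(seed = 17, missing_plant_prob = 0.4)
  sc_m <- generate_scene(cfg_missing)
  grid <- build_plant_grid(sc$roi, cfg$plants_per_row, cfg$n_rows,
                           cfg$row_azimuth)
  canopy <- subset_cloud(sc$cloud, sc$cloud$class_label == "canopy")
  vols <- plant_volumes(grid, canopy)
  m <- merge(vols, sc$plant_truth, by = "plant_id")
  ratio <- m$hull_volume / m$true_volume
  expect_true(all(ratio >= 0.90 & ratio <= 1.00))

  grid_m <- build_plant_grid(sc_m$roi, cfg_missing$plants_per_row,
                             cfg_missing$n_rows, cfg_missing$row_azimuth)
  canopy_m <- subset_cloud(sc_m$cloud, sc_m$cloud$class_label == "canopy")
  vols_m <- plant_volumes(grid_m, canopy_m)
  missing <- merge(vols_m, sc_m$plant_truth, by = "plant_id")
  missing <- missing[!missing$present, ]
  expect_gt(nrow(missing), 0)
  expect_true(all(missing$n_points == 0))
  expect_true(all(is.na(missing$hull_volume)))
})
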