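test_that("scene generation is a pure function of its config", {
  cfg <- small_scene_config(seed = 5)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$cloud$coords, b$cloud$coords)
  expect_identical(a$cloud$temperature, b$cloud$temperature)
  expect_identical(a$thermal$values, b$thermal$values)
  expect_identical(a$plant_truth, b$plant_truth)
  # and a different seed changes the scene
  c <- generate_scene(small_scene_config(seed = 6))
  expect_false(identical(a$cloud$coords, c$cloud$coords))
})

test_that("all plants missing gives a bare-terrain scene", {
  sc <- generate_scene(small_scene_config(seed = 2, missing_plant_prob = 1))
  expect_identical(sum(sc$cloud$class_label == "canopy"), 0L)
  expect_identical(sc$dsm$values, sc$dtm$values)
  expect_true(all(sc$plant_truth$true_volume == 0))
})

test_that("noise-free canopy temperatures equal the deterministic field", {
  cfg <- small_scene_config(seed = 3, temp_noise_sd = 0, soil_temp_sd = 0,
                            plant_scale_sd = 0)
  sc <- generate_scene(cfg)
  can <- sc$cloud$class_label == "canopy"
  # reconstruct depth below each plant's canopy top from the truth table
  coords <- sc$cloud$coords[can, , drop = FALSE]
  truth <- sc$plant_truth
  nearest <- apply(coords[, 1:2], 1, function(p)
    which.min((truth$x - p[1])^2 + (truth$y - p[2])^2))
  top <- vinecwsi:::terrain_z(cfg, truth$x[nearest], truth$y[nearest]) +
    cfg$canopy_base + cfg$canopy_height
  depth <- top - coords[, 3]
  expected <- cfg$canopy_top_temp_mean + cfg$vertical_temp_gradient * depth
  expect_equal(sc$cloud$temperature[can], expected, tolerance = 1e-12)
  # soil is warmer than every canopy point by construction
  expect_gt(min(sc$cloud$temperature[!can]), max(sc$cloud$temperature[can]))
})

test_that("ellipsoid segment volume matches a Monte-Carlo rejection oracle", {
  # radii (1.0, 0.6) and a 1.5 m height interval
  a <- 1.0; b <- 0.6; c <- 0.75
  v_full <- ellipsoid_segment_volume(a, b, c)
  expect_equal(v_full, 4 / 3 * pi * a * b * c, tolerance = 1e-12)
  # truncated segment: bottom quarter cut away
  v_seg <- ellipsoid_segment_volume(a, b, c, z_lo = -c / 2)
  set.seed(99)
  n <- 4e5
  pts <- cbind(runif(n, -a, a), runif(n, -b, b), runif(n, -c / 2, c))
  inside <- (pts[, 1] / a)^2 + (pts[, 2] / b)^2 + (pts[, 3] / c)^2 <= 1
  v_mc <- mean(inside) * (2 * a) * (2 * b) * (1.5 * c)
  expect_equal(v_seg, v_mc, tolerance = 0.01)
  # degenerate interval
  expect_identical(ellipsoid_segment_volume(a, b, c, z_lo = c, z_hi = c), 0)
})

test_that("canopy points reproduce the envelope's height distribution", {
  # lower the canopy base below the 0.5 m threshold so the fraction bites
  cfg <- small_scene_config(seed = 8, canopy_base = 0.2, point_density = 300,
                            missing_plant_prob = 0, plant_scale_sd = 0)
  sc <- generate_scene(cfg)
  can <- sc$cloud$class_label == "canopy"
  coords <- sc$cloud$coords[can, , drop = FALSE]
  truth <- sc$plant_truth
  nearest <- apply(coords[, 1:2], 1, function(p)
    which.min((truth$x - p[1])^2 + (truth$y - p[2])^2))
  h <- coords[, 3] - vinecwsi:::terrain_z(cfg, truth$x[nearest], truth$y[nearest])
  frac <- mean(h > 0.5)
  # independent oracle: Monte-Carlo area fraction of the ellipsoid surface
  # above 0.5 m (area-weighted rejection on the sphere map)
  set.seed(1234)
  aa <- cfg$canopy_radii[1]; bb <- cfg$canopy_radii[2]
  cc <- cfg$canopy_height / 2
  g <- matrix(rnorm(3 * 2e5), ncol = 3)
  g <- g / sqrt(rowSums(g^2))
  w <- sqrt((g[, 1] * bb * cc)^2 + (g[, 2] * aa * cc)^2 + (g[, 3] * aa * bb)^2)
  z <- cc * g[, 3] + cfg$canopy_base + cfg$canopy_height / 2  # height above terrain
  keep <- z >= cfg$canopy_base
  frac_oracle <- sum(w[keep & z > 0.5]) / sum(w[keep])
  expect_equal(frac, frac_oracle, tolerance = 0.02)
})

test_that("the DSM dominates the DTM and the vertical gradient is cool-topped", {
  cfg <- small_scene_config(seed = 4, temp_noise_sd = 0, soil_temp_sd = 0)
  sc <- generate_scene(cfg)
  expect_true(all(sc$dsm$values >= sc$dtm$values - 1e-12))
  can <- which(sc$cloud$class_label == "canopy")
  z <- sc$cloud$coords[can, 3]
  temp <- sc$cloud$temperature[can]
  truth <- sc$plant_truth
  nearest <- apply(sc$cloud$coords[can, 1:2, drop = FALSE], 1, function(p)
    which.min((truth$x - p[1])^2 + (truth$y - p[2])^2))
  # within every plant the coolest point is the highest one (canopy-top
  # minimum of the vertical gradient)
  for (k in unique(nearest)) {
    i <- nearest == k
    expect_equal(which.min(temp[i]), which.max(z[i]))
  }
})

test_that("scenes round-trip through disk and the manifest tracks the config", {
  cfg <- small_scene_config(seed = 9)
  sc <- generate_scene(cfg)
  d1 <- file.path(tempdir(), "scene_a")
  man1 <- scene_to_disk(sc, d1)
  back <- scene_from_disk(d1)
  expect_equal(back$dtm$values, sc$dtm$values)
  expect_equal(back$thermal$values, sc$thermal$values)
  expect_cloud_equal(back$cloud, sc$cloud)
  expect_equal(back$plant_truth$true_volume, sc$plant_truth$true_volume)
  expect_equal(back$config$seed, 9)

  # identical seeds give byte-identical text clouds
  d2 <- file.path(tempdir(), "scene_b")
  scene_to_disk(generate_scene(cfg), d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "cloud.xyz"))),
                   unname(tools::md5sum(file.path(d2, "cloud.xyz"))))
  # changing one parameter changes the config digest
  sc3 <- generate_scene(small_scene_config(seed = 9, canopy_height = 1.9))
  d3 <- file.path(tempdir(), "scene_c")
  man3 <- scene_to_disk(sc3, d3)
  expect_false(identical(man1$config_md5, man3$config_md5))
})

test_that("scene_config rejects invalid parameter combinations", {
  expect_error(scene_config(row_spacing = -1), "positive|> 0")
  expect_error(scene_config(missing_plant_prob = 1.2), "\\[0, 1\\]")
  expect_error(scene_config(point_density = 0), "> 0")
  expect_error(scene_config(canopy_radii = 1), "along, across")
})
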